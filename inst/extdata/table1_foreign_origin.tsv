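origin	continent	percent
Romania	Europe	14
United Kingdom	Europe	7
Germany	Europe	3
Italy	Europe	3
Other Europe	Europe	18
Morocco	Africa	12
Other Africa	Africa	5
Ecuador	Americas	8
Colombia	Americas	5
Bolivia	Americas	5
Argentina	Americas	3
Other Americas	Americas	13
China	Asia	2
Other Asia	Asia	2
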