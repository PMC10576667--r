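"municipality_id","name","x","y"
"M0001","Municipality 0001",48558.5135407746,85121.1223052815
"M0002","Municipality 0002",38165.2226205915,85746.3751221076
"M0003","Municipality 0003",89101.5218105167,73968.4720523655
"M0004","Municipality 0004",16378.996684216,35309.9695872515
"M0005","Municipality 0005",47413.4463118389,67337.3083118349
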