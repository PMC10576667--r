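"dwelling_id","capacity"
"T00001",9
"T00002",6
"T00003",17
"T00004",2
"T00005",18
"T00006",4
"T00007",3
"T00008",7
"T00009",16
"T00010",10
"T00011",34
"T00012",7
"T00013",3
"T00014",29
"T00015",12
"T00016",2
"T00017",10
"T00018",9
"T00019",4
"T00020",17
"T00021",2
"T00022",5
"T00023",5
"T00024",24
"T00025",3
"T00026",25
"T00027",16
"T00028",16
"T00029",13
"T00030",8
"T00031",4
"T00032",7
"T00033",6
"T00034",3
"T00035",3
"T00036",8
"T00037",10
"T00038",7
"T00039",8
"T00040",5
"T00041",2
"T00042",43
"T00043",8
"T00044",5
"T00045",4
"T00046",8
"T00047",7
"T00048",10
"T00049",10
"T00050",6
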