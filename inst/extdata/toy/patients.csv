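"patient_id","sex","age_class","birth_date","onset_date","diagnosis_date","genetic_status","relatedness_group"
"P00001","F","75-84",1929-12-17,2011-10-08,2012-06-23,"positive",NA
"P00002","M","75-84",1931-10-28,2013-08-06,2014-06-20,"wild-type",NA
"P00003","M","75-84",1928-10-04,2008-07-31,2009-03-09,"wild-type",NA
"P00004","F","35-44",1966-07-04,2008-06-29,2009-01-19,"wild-type",NA
"P00005","F","65-74",1934-06-04,2007-12-21,2008-05-12,"positive",NA
"P00006","F","45-54",1960-11-11,2012-01-19,2012-05-28,"missing",NA
"P00007","F","75-84",1930-05-30,2007-11-24,2008-04-25,"wild-type",NA
"P00008","M","75-84",1933-05-12,2011-04-17,2011-12-05,"wild-type",NA
"P00009","M","45-54",1967-12-16,2013-10-13,2014-10-07,"wild-type",NA
"P00010","F","65-74",1934-05-05,2007-01-21,2007-07-29,"wild-type",NA
"P00011","F","65-74",1939-05-07,2010-11-11,2012-04-04,"wild-type",NA
"P00012","M","0-24",1987-01-22,2009-06-14,2009-10-20,"missing",NA
"P00013","F","55-64",1948-03-10,2010-03-20,2010-07-05,"wild-type",NA
"P00014","M","75-84",1929-04-25,2012-10-09,2013-02-27,"positive",NA
"P00015","M","35-44",1962-06-05,2007-03-27,2007-10-27,"wild-type",NA
"P00016","F","35-44",1969-12-27,2014-01-02,2014-10-09,"missing",NA
"P00017","M","75-84",1933-10-24,2010-05-22,2010-12-17,"missing",NA
"P00018","F","65-74",1938-04-20,2011-07-05,2012-05-28,"missing",NA
"P00019","M","45-54",1962-10-13,2011-01-10,2012-04-06,"wild-type",NA
"P00020","F","45-54",1961-02-24,2013-07-20,2014-01-04,"missing",NA
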