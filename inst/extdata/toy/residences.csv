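"patient_id","dwelling_id","municipality_id","start_date","end_date"
"P00001","DW-P00001-01","M0001",1961-10-08,1971-10-07
"P00001","DW-P00001-02","M0003",1971-10-08,1979-10-07
"P00001","DW-P00001-03","M0004",1979-10-08,1992-10-07
"P00001","DW-P00001-04","M0005",1992-10-08,2008-10-07
"P00001","DW-P00001-05","M0004",2008-10-08,2012-07-23
"P00002","DW-P00002-01","M0001",1963-08-06,1965-08-05
"P00002","DW-P00002-02","M0005",1965-08-06,1968-08-05
"P00002","DW-P00002-03","M0001",1968-08-06,1982-08-05
"P00002","DW-P00002-04","M0004",1982-08-06,1990-08-05
"P00002","DW-P00002-05","M0003",1990-08-06,2014-07-20
"P00003","DW-P00003-01","M0004",1958-07-31,1980-07-30
"P00003","DW-P00003-02","M0005",1980-07-31,2002-07-30
"P00003","DW-P00003-03","M0003",2002-07-31,2005-07-30
"P00003","DW-P00003-04","M0004",2005-07-31,2009-04-08
"P00004","DW-P00004-01","M0003",1967-06-29,1975-06-28
"P00004","DW-P00004-02","M0004",1975-06-29,2006-06-28
"P00004","DW-P00004-03","M0003",2006-06-29,2009-02-18
"P00005","DW-P00005-01","M0003",1972-12-21,1976-12-20
"P00005","DW-P00005-02","M0005",1976-12-21,1984-12-20
"P00005","DW-P00005-03","M0004",1984-12-21,2008-06-11
"P00006","DW-P00006-01","M0003",1962-01-19,1963-01-18
"P00006","DW-P00006-02","M0004",1963-01-19,1983-01-18
"P00006","DW-P00006-03","M0005",1983-01-19,2002-01-18
"P00006","DW-P00006-04","M0004",2002-01-19,2012-06-27
"P00007","DW-P00007-01","M0003",1957-11-24,1971-11-23
"P00007","DW-P00007-02","M0004",1971-11-24,1975-11-23
"P00007","DW-P00007-03","M0003",1975-11-24,2008-05-25
"P00008","DW-P00008-01","M0005",1972-04-17,1977-04-16
"P00008","DW-P00008-02","M0004",1977-04-17,1988-04-16
"P00008","DW-P00008-03","M0005",1988-04-17,1998-04-16
"P00008","DW-P00008-04","M0003",1998-04-17,2012-01-04
"P00009","DW-P00009-01","M0003",1968-10-13,1971-10-12
"P00009","DW-P00009-02","M0005",1971-10-13,1985-10-12
"P00009","DW-P00009-03","M0004",1985-10-13,2014-11-06
"P00010","DW-P00010-01","M0004",1957-01-21,1981-01-20
"P00010","DW-P00010-02","M0003",1981-01-21,1994-01-20
"P00010","DW-P00010-03","M0004",1994-01-21,1997-01-20
"P00010","DW-P00010-04","M0001",1997-01-21,1998-01-20
"P00010","DW-P00010-05","M0003",1998-01-21,2007-08-28
"P00011","DW-P00011-01","M0001",1960-11-11,1990-11-10
"P00011","DW-P00011-02","M0005",1990-11-11,1994-11-10
"P00011","DW-P00011-03","M0003",1994-11-11,2005-11-10
"P00011","DW-P00011-04","M0005",2005-11-11,2012-05-04
"P00012","DW-P00012-01","M0005",1987-06-14,1993-06-13
"P00012","DW-P00012-02","M0004",1993-06-14,2009-11-19
"P00013","DW-P00013-01","M0001",1960-03-20,1965-03-19
"P00013","DW-P00013-02","M0004",1965-03-20,2000-03-19
"P00013","DW-P00013-03","M0001",2000-03-20,2010-08-04
"P00014","DW-P00014-01","M0004",1992-10-09,2007-10-08
"P00014","DW-P00014-02","M0001",2007-10-09,2010-10-08
"P00014","DW-P00014-03","M0003",2010-10-09,2013-03-29
"P00015","DW-P00015-01","M0003",1963-03-27,1992-03-26
"P00015","DW-P00015-02","M0001",1992-03-27,2007-11-26
"P00016","DW-P00016-01","M0004",1970-01-02,1983-01-01
"P00016","DW-P00016-02","M0003",1983-01-02,1986-01-01
"P00016","DW-P00016-03","M0004",1986-01-02,2010-01-01
"P00016","DW-P00016-04","M0001",2010-01-02,2012-01-01
"P00016","DW-P00016-05","M0003",2012-01-02,2014-11-08
"P00017","DW-P00017-01","M0003",1960-05-22,1963-05-21
"P00017","DW-P00017-02","M0001",1963-05-22,1967-05-21
"P00017","DW-P00017-03","M0003",1967-05-22,1980-05-21
"P00017","DW-P00017-04","M0004",1980-05-22,2011-01-16
"P00018","DW-P00018-01","M0001",1961-07-05,1991-07-04
"P00018","DW-P00018-02","M0003",1991-07-05,2007-07-04
"P00018","DW-P00018-03","M0001",2007-07-05,2012-06-27
"P00019","DW-P00019-01","M0003",1966-01-10,1972-01-09
"P00019","DW-P00019-02","M0004",1972-01-10,1991-01-09
"P00019","DW-P00019-03","M0003",1991-01-10,2012-05-06
"P00020","DW-P00020-01","M0001",1963-07-20,2006-07-19
"P00020","DW-P00020-02","M0003",2006-07-20,2014-02-03
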