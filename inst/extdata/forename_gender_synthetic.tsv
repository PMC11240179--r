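name	year	prop_female
James	1930	0.003
James	1940	0.003
James	1950	0.004
James	1960	0.004
James	1970	0.004
James	1980	0.005
James	1990	0.005
James	2000	0.005
James	2010	0.006
James	2012	0.006
John	1930	0.003
John	1940	0.003
John	1950	0.004
John	1960	0.004
John	1970	0.004
John	1980	0.005
John	1990	0.005
John	2000	0.005
John	2010	0.006
John	2012	0.006
Robert	1930	0.003
Robert	1940	0.003
Robert	1950	0.004
Robert	1960	0.004
Robert	1970	0.004
Robert	1980	0.005
Robert	1990	0.005
Robert	2000	0.005
Robert	2010	0.006
Robert	2012	0.006
Michael	1930	0.003
Michael	1940	0.003
Michael	1950	0.004
Michael	1960	0.004
Michael	1970	0.004
Michael	1980	0.005
Michael	1990	0.005
Michael	2000	0.005
Michael	2010	0.006
Michael	2012	0.006
William	1930	0.003
William	1940	0.003
William	1950	0.004
William	1960	0.004
William	1970	0.004
William	1980	0.005
William	1990	0.005
William	2000	0.005
William	2010	0.006
William	2012	0.006
David	1930	0.003
David	1940	0.003
David	1950	0.004
David	1960	0.004
David	1970	0.004
David	1980	0.005
David	1990	0.005
David	2000	0.005
David	2010	0.006
David	2012	0.006
Richard	1930	0.003
Richard	1940	0.003
Richard	1950	0.004
Richard	1960	0.004
Richard	1970	0.004
Richard	1980	0.005
Richard	1990	0.005
Richard	2000	0.005
Richard	2010	0.006
Richard	2012	0.006
Thomas	1930	0.003
Thomas	1940	0.003
Thomas	1950	0.004
Thomas	1960	0.004
Thomas	1970	0.004
Thomas	1980	0.005
Thomas	1990	0.005
Thomas	2000	0.005
Thomas	2010	0.006
Thomas	2012	0.006
Charles	1930	0.003
Charles	1940	0.003
Charles	1950	0.004
Charles	1960	0.004
Charles	1970	0.004
Charles	1980	0.005
Charles	1990	0.005
Charles	2000	0.005
Charles	2010	0.006
Charles	2012	0.006
Daniel	1930	0.003
Daniel	1940	0.003
Daniel	1950	0.004
Daniel	1960	0.004
Daniel	1970	0.004
Daniel	1980	0.005
Daniel	1990	0.005
Daniel	2000	0.005
Daniel	2010	0.006
Daniel	2012	0.006
Mary	1930	0.995
Mary	1940	0.995
Mary	1950	0.995
Mary	1960	0.994
Mary	1970	0.994
Mary	1980	0.994
Mary	1990	0.994
Mary	2000	0.993
Mary	2010	0.993
Mary	2012	0.993
Patricia	1930	0.995
Patricia	1940	0.995
Patricia	1950	0.995
Patricia	1960	0.994
Patricia	1970	0.994
Patricia	1980	0.994
Patricia	1990	0.994
Patricia	2000	0.993
Patricia	2010	0.993
Patricia	2012	0.993
Linda	1930	0.995
Linda	1940	0.995
Linda	1950	0.995
Linda	1960	0.994
Linda	1970	0.994
Linda	1980	0.994
Linda	1990	0.994
Linda	2000	0.993
Linda	2010	0.993
Linda	2012	0.993
Barbara	1930	0.995
Barbara	1940	0.995
Barbara	1950	0.995
Barbara	1960	0.994
Barbara	1970	0.994
Barbara	1980	0.994
Barbara	1990	0.994
Barbara	2000	0.993
Barbara	2010	0.993
Barbara	2012	0.993
Susan	1930	0.995
Susan	1940	0.995
Susan	1950	0.995
Susan	1960	0.994
Susan	1970	0.994
Susan	1980	0.994
Susan	1990	0.994
Susan	2000	0.993
Susan	2010	0.993
Susan	2012	0.993
Jennifer	1930	0.995
Jennifer	1940	0.995
Jennifer	1950	0.995
Jennifer	1960	0.994
Jennifer	1970	0.994
Jennifer	1980	0.994
Jennifer	1990	0.994
Jennifer	2000	0.993
Jennifer	2010	0.993
Jennifer	2012	0.993
Elizabeth	1930	0.995
Elizabeth	1940	0.995
Elizabeth	1950	0.995
Elizabeth	1960	0.994
Elizabeth	1970	0.994
Elizabeth	1980	0.994
Elizabeth	1990	0.994
Elizabeth	2000	0.993
Elizabeth	2010	0.993
Elizabeth	2012	0.993
Maria	1930	0.995
Maria	1940	0.995
Maria	1950	0.995
Maria	1960	0.994
Maria	1970	0.994
Maria	1980	0.994
Maria	1990	0.994
Maria	2000	0.993
Maria	2010	0.993
Maria	2012	0.993
Sarah	1930	0.995
Sarah	1940	0.995
Sarah	1950	0.995
Sarah	1960	0.994
Sarah	1970	0.994
Sarah	1980	0.994
Sarah	1990	0.994
Sarah	2000	0.993
Sarah	2010	0.993
Sarah	2012	0.993
Karen	1930	0.995
Karen	1940	0.995
Karen	1950	0.995
Karen	1960	0.994
Karen	1970	0.994
Karen	1980	0.994
Karen	1990	0.994
Karen	2000	0.993
Karen	2010	0.993
Karen	2012	0.993
Leslie	1930	0.2
Leslie	1940	0.3
Leslie	1950	0.42
Leslie	1960	0.55
Leslie	1970	0.68
Leslie	1980	0.8
Leslie	1990	0.88
Leslie	2000	0.91
Leslie	2010	0.93
Leslie	2012	0.93
Taylor	1930	0.15
Taylor	1940	0.2
Taylor	1950	0.28
Taylor	1960	0.36
Taylor	1970	0.45
Taylor	1980	0.55
Taylor	1990	0.65
Taylor	2000	0.72
Taylor	2010	0.75
Taylor	2012	0.76
Jamie	1930	0.3
Jamie	1940	0.34
Jamie	1950	0.4
Jamie	1960	0.47
Jamie	1970	0.54
Jamie	1980	0.58
Jamie	1990	0.6
Jamie	2000	0.61
Jamie	2010	0.62
Jamie	2012	0.62
Casey	1930	0.25
Casey	1940	0.28
Casey	1950	0.33
Casey	1960	0.4
Casey	1970	0.46
Casey	1980	0.51
Casey	1990	0.54
Casey	2000	0.55
Casey	2010	0.56
Casey	2012	0.56
Alex	1930	0.05
Alex	1940	0.072
Alex	1950	0.094
Alex	1960	0.117
Alex	1970	0.139
Alex	1980	0.161
Alex	1990	0.183
Alex	2000	0.206
Alex	2010	0.228
Alex	2012	0.25
Jordan	1930	0.1
Jordan	1940	0.139
Jordan	1950	0.178
Jordan	1960	0.217
Jordan	1970	0.256
Jordan	1980	0.294
Jordan	1990	0.333
Jordan	2000	0.372
Jordan	2010	0.411
Jordan	2012	0.45
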