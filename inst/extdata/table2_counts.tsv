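group	rs_id	genotype	count
controls	rs4341	DD	49
controls	rs4341	ID	200
controls	rs4341	II	167
controls	rs1815739	CC	84
controls	rs1815739	CT	226
controls	rs1815739	TT	106
controls	rs671	GG	232
controls	rs671	GA	149
controls	rs671	AA	35
controls	rs4950	AA	323
controls	rs4950	GA	77
controls	rs4950	GG	16
controls	rs8111989	AA	308
controls	rs8111989	GA	98
controls	rs8111989	GG	10
controls	rs41274853	CC	210
controls	rs41274853	CT	170
controls	rs41274853	TT	36
controls	rs9939609	TT	269
controls	rs9939609	TA	130
controls	rs9939609	AA	17
controls	rs558129	CC	304
controls	rs558129	CT	101
controls	rs558129	TT	11
controls	rs680	CC	143
controls	rs680	CT	193
controls	rs680	TT	80
controls	rs1049434	AA	199
controls	rs1049434	TA	175
controls	rs1049434	TT	42
controls	rs8192678	AA	79
controls	rs8192678	GA	184
controls	rs8192678	GG	153
controls	rs7832552	TT	129
controls	rs7832552	CT	175
controls	rs7832552	CC	112
weightlifters	rs4341	DD	40
weightlifters	rs4341	ID	79
weightlifters	rs4341	II	73
weightlifters	rs1815739	CC	49
weightlifters	rs1815739	CT	86
weightlifters	rs1815739	TT	57
weightlifters	rs671	GG	99
weightlifters	rs671	GA	76
weightlifters	rs671	AA	17
weightlifters	rs4950	AA	127
weightlifters	rs4950	GA	61
weightlifters	rs4950	GG	4
weightlifters	rs8111989	AA	152
weightlifters	rs8111989	GA	34
weightlifters	rs8111989	GG	6
weightlifters	rs41274853	CC	104
weightlifters	rs41274853	CT	64
weightlifters	rs41274853	TT	24
weightlifters	rs9939609	TT	118
weightlifters	rs9939609	TA	65
weightlifters	rs9939609	AA	9
weightlifters	rs558129	CC	137
weightlifters	rs558129	CT	49
weightlifters	rs558129	TT	6
weightlifters	rs680	CC	80
weightlifters	rs680	CT	83
weightlifters	rs680	TT	29
weightlifters	rs1049434	AA	75
weightlifters	rs1049434	TA	91
weightlifters	rs1049434	TT	26
weightlifters	rs8192678	AA	35
weightlifters	rs8192678	GA	102
weightlifters	rs8192678	GG	55
weightlifters	rs7832552	TT	52
weightlifters	rs7832552	CT	98
weightlifters	rs7832552	CC	42
international	rs4341	DD	12
international	rs4341	ID	22
international	rs4341	II	33
international	rs1815739	CC	21
international	rs1815739	CT	31
international	rs1815739	TT	15
international	rs671	GG	34
international	rs671	GA	26
international	rs671	AA	7
international	rs4950	AA	47
international	rs4950	GA	19
international	rs4950	GG	1
international	rs8111989	AA	52
international	rs8111989	GA	13
international	rs8111989	GG	2
international	rs41274853	CC	26
international	rs41274853	CT	28
international	rs41274853	TT	13
international	rs9939609	TT	44
international	rs9939609	TA	21
international	rs9939609	AA	2
international	rs558129	CC	48
international	rs558129	CT	17
international	rs558129	TT	2
international	rs680	CC	25
international	rs680	CT	32
international	rs680	TT	10
international	rs1049434	AA	28
international	rs1049434	TA	30
international	rs1049434	TT	9
international	rs8192678	AA	13
international	rs8192678	GA	38
international	rs8192678	GG	16
international	rs7832552	TT	13
international	rs7832552	CT	32
international	rs7832552	CC	22
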