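population,year,singer_id,cycle_index,position,theme_label
Gabon,2001,1,1,1,1
Gabon,2001,1,1,2,4
Gabon,2001,1,1,3,5
Gabon,2001,1,1,4,11
Gabon,2001,1,1,5,1
Gabon,2001,1,1,6,3
Gabon,2001,2,1,1,1
Gabon,2001,2,1,2,2
Gabon,2001,2,1,3,3
Gabon,2001,2,1,4,2
Madagascar,2001,3,1,1,1
Madagascar,2001,3,1,2,2
Madagascar,2001,3,1,3,3
Madagascar,2001,3,1,4,2
Madagascar,2001,2,1,1,1
Madagascar,2001,2,1,2,3
Madagascar,2001,2,1,3,2
Gabon,2002,1,1,1,7c
Gabon,2002,1,1,2,8
Gabon,2002,1,1,3,10
Gabon,2002,1,1,4,14
Gabon,2002,1,1,5,7
Madagascar,2002,1,1,1,7c
Madagascar,2002,1,1,2,12
Madagascar,2002,1,1,3,13
Madagascar,2002,2,1,1,7c
Madagascar,2002,2,1,2,13
Madagascar,2002,2,1,3,12
Madagascar,2002,2,1,4,13
Madagascar,2002,8,1,1,7c
Madagascar,2002,8,1,2,29
Madagascar,2002,8,1,3,12
Madagascar,2002,8,1,4,14
Madagascar,2002,8,1,5,10
Gabon,2003,1,1,1,7s
Gabon,2003,1,1,2,16
Gabon,2003,1,1,3,18
Gabon,2003,1,1,4,19s
Gabon,2003,1,1,5,14
Gabon,2003,1,1,6,6
Gabon,2003,1,1,7,20
Gabon,2003,3,1,1,7s
Gabon,2003,3,1,2,16
Gabon,2003,3,1,3,18
Gabon,2003,3,1,4,19s
Gabon,2003,3,1,5,14
Gabon,2003,3,1,6,6
Gabon,2003,3,1,7,20
Gabon,2003,4,1,1,7s
Gabon,2003,4,1,2,16
Gabon,2003,4,1,3,18
Gabon,2003,4,1,4,19s
Gabon,2003,4,1,5,14
Gabon,2003,4,1,6,6
Gabon,2003,4,1,7,20
Gabon,2003,6,1,1,7s
Gabon,2003,6,1,2,16
Gabon,2003,6,1,3,15
Gabon,2003,6,1,4,18
Gabon,2003,6,1,5,19s
Gabon,2003,6,1,6,14
Gabon,2003,6,1,7,6
Gabon,2003,6,1,8,20
Madagascar,2003,6,1,1,7s
Madagascar,2003,6,1,2,21
Madagascar,2003,6,1,3,15
Madagascar,2003,6,1,4,14
Madagascar,2003,9,1,1,7s
Madagascar,2003,9,1,2,21
Madagascar,2003,9,1,3,15
Madagascar,2003,9,1,4,6
Madagascar,2003,9,1,5,14
Madagascar,2003,10,1,1,7s
Madagascar,2003,10,1,2,21
Madagascar,2003,10,1,3,15
Madagascar,2003,10,1,4,14
Madagascar,2003,13,1,1,7s
Madagascar,2003,13,1,2,21
Madagascar,2003,13,1,3,15
Madagascar,2003,13,1,4,6
Gabon,2004,1,1,1,7s
Gabon,2004,1,1,2,23
Gabon,2004,1,1,3,17
Gabon,2004,1,1,4,25
Gabon,2004,1,1,5,18E
Gabon,2004,1,1,6,24
Gabon,2004,1,1,7,6
Gabon,2004,3,1,1,7s
Gabon,2004,3,1,2,23
Gabon,2004,3,1,3,17
Gabon,2004,3,1,4,25
Gabon,2004,3,1,5,24
Gabon,2004,5,1,1,7s
Gabon,2004,5,1,2,23
Gabon,2004,5,1,3,25
Gabon,2004,5,1,4,18E
Gabon,2004,5,1,5,24
Gabon,2004,5,1,6,6
Madagascar,2004,1,1,1,7s
Madagascar,2004,1,1,2,23
Madagascar,2004,1,1,3,24
Madagascar,2004,1,1,4,25
Madagascar,2004,1,1,5,6
Madagascar,2004,8,1,1,7s
Madagascar,2004,8,1,2,23
Madagascar,2004,8,1,3,24
Madagascar,2004,8,1,4,25
Madagascar,2004,8,1,5,6
Madagascar,2004,9,1,1,7s
Madagascar,2004,9,1,2,23
Madagascar,2004,9,1,3,24
Madagascar,2004,9,1,4,25
Madagascar,2004,9,1,5,6
Madagascar,2004,11,1,1,7s
Madagascar,2004,11,1,2,23
Madagascar,2004,11,1,3,24
Madagascar,2004,11,1,4,25
Madagascar,2004,11,1,5,6
Gabon,2005,7,1,1,7s
Gabon,2005,7,1,2,23E
Gabon,2005,7,1,3,24
Gabon,2005,7,1,4,6
Gabon,2005,8,1,1,7s
Gabon,2005,8,1,2,26
Gabon,2005,8,1,3,24
Gabon,2005,8,1,4,27
Gabon,2005,2,1,1,7s
Gabon,2005,2,1,2,26
Gabon,2005,2,1,3,24
Gabon,2005,3,1,1,7s
Gabon,2005,3,1,2,26
Gabon,2005,3,1,3,27
Gabon,2005,3,1,4,24
Madagascar,2005,15,1,1,7s
Madagascar,2005,15,1,2,26
Madagascar,2005,15,1,3,24
Madagascar,2005,15,1,4,27
Madagascar,2005,10,1,1,7s
Madagascar,2005,10,1,2,26
Madagascar,2005,10,1,3,24
Madagascar,2005,10,1,4,27
Madagascar,2005,18,1,1,7s
Madagascar,2005,18,1,2,23E
Madagascar,2005,18,1,3,26
Madagascar,2005,18,1,4,24
Madagascar,2005,18,1,5,27
Madagascar,2005,19,1,1,7s
Madagascar,2005,19,1,2,26
Madagascar,2005,19,1,3,24
Madagascar,2005,19,1,4,27
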