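LABEL,ID,TRACK_ID,QUALITY,POSITION_X,POSITION_Y,POSITION_Z,POSITION_T,FRAME
Label,Spot ID,Track ID,Quality,X,Y,Z,T,Frame
Label,Spot ID,Track ID,Quality,(micron),(micron),(micron),(sec),
,,,,,,,,
ID1000,1000,0,1.2,10.0,20.0,0,0.000,0
ID1001,1001,0,1.1,11.0,20.5,0,0.033,1
ID1002,1002,0,1.3,12.1,21.0,0,0.067,2
ID1003,1003,0,1.2,13.0,21.4,0,0.100,3
ID2000,2000,1,0.9,50.0,60.0,0,0.000,0
ID2001,2001,1,1.0,50.2,59.5,0,0.033,1
ID2002,2002,1,0.8,50.1,59.0,0,0.067,2
ID2003,2003,1,0.9,50.4,58.4,0,0.100,3
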