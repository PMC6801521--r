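"residue","hydrophobicity","charge","volume","polarity"
"Ala",0.31,0,88.6,"nonpolar"
"Arg",-1.01,1,173.4,"polar"
"Asn",-0.6,0,114.1,"polar"
"Asp",-0.77,-1,111.1,"polar"
"Cys",1.54,0,108.5,"polar"
"Gln",-0.22,0,143.8,"polar"
"Glu",-0.64,-1,138.4,"polar"
"Gly",0,0,60.1,"nonpolar"
"His",0.13,0,153.2,"polar"
"Ile",1.8,0,166.7,"nonpolar"
"Leu",1.7,0,166.7,"nonpolar"
"Lys",-0.99,1,168.6,"polar"
"Met",1.23,0,162.9,"nonpolar"
"Phe",1.79,0,189.9,"nonpolar"
"Pro",0.72,0,112.7,"nonpolar"
"Ser",-0.04,0,89,"polar"
"Thr",0.26,0,116.1,"polar"
"Trp",2.25,0,227.8,"nonpolar"
"Tyr",0.96,0,193.6,"polar"
"Val",1.22,0,140,"nonpolar"
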