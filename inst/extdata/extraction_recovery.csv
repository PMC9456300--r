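"ion","label","method","recovery","sd"
653.26,"5'N-10+3'N-5 or 5'N-9+3'N-6","SPE",91,2
1307.52,"5'N-10+3'N-5 or 5'N-9+3'N-6","SPE",92,1
661.24,"5'N-11+3'N-4","SPE",93,3
1323.5,"5'N-11+3'N-4","SPE",94,4
617.73,"5'N-11+3'N-4","SPE",98,3
1236.46,"5'N-11+3'N-4","SPE",97,4
696.76,"5'N-15+3'N-1 or 5'N-12+3'N-3","SPE",96,4
1394.54,"5'N-15+3'N-1 or 5'N-12+3'N-3","SPE",96,3
771.29,"3'N-14","SPE",90,4
1543.59,"3'N-14","SPE",91,5
653.26,"5'N-10+3'N-5 or 5'N-9+3'N-6","MEPS_SDVB",85,1
1307.52,"5'N-10+3'N-5 or 5'N-9+3'N-6","MEPS_SDVB",87,2
661.24,"5'N-11+3'N-4","MEPS_SDVB",84,2
1323.5,"5'N-11+3'N-4","MEPS_SDVB",84,2
617.73,"5'N-11+3'N-4","MEPS_SDVB",86,1
1236.46,"5'N-11+3'N-4","MEPS_SDVB",83,2
696.76,"5'N-15+3'N-1 or 5'N-12+3'N-3","MEPS_SDVB",80,1
1394.54,"5'N-15+3'N-1 or 5'N-12+3'N-3","MEPS_SDVB",81,1
771.29,"3'N-14","MEPS_SDVB",86,1
1543.59,"3'N-14","MEPS_SDVB",86,2
653.26,"5'N-10+3'N-5 or 5'N-9+3'N-6","MEPS_C18",78,2
1307.52,"5'N-10+3'N-5 or 5'N-9+3'N-6","MEPS_C18",80,1
661.24,"5'N-11+3'N-4","MEPS_C18",77,1
1323.5,"5'N-11+3'N-4","MEPS_C18",76,1
617.73,"5'N-11+3'N-4","MEPS_C18",80,2
1236.46,"5'N-11+3'N-4","MEPS_C18",78,3
696.76,"5'N-15+3'N-1 or 5'N-12+3'N-3","MEPS_C18",79,1
1394.54,"5'N-15+3'N-1 or 5'N-12+3'N-3","MEPS_C18",78,1
771.29,"3'N-14","MEPS_C18",76,2
1543.59,"3'N-14","MEPS_C18",75,2
653.26,"5'N-10+3'N-5 or 5'N-9+3'N-6","MNP",66,5
1307.52,"5'N-10+3'N-5 or 5'N-9+3'N-6","MNP",63,2
661.24,"5'N-11+3'N-4","MNP",66,3
1323.5,"5'N-11+3'N-4","MNP",63,4
617.73,"5'N-11+3'N-4","MNP",65,4
1236.46,"5'N-11+3'N-4","MNP",65,4
696.76,"5'N-15+3'N-1 or 5'N-12+3'N-3","MNP",63,5
1394.54,"5'N-15+3'N-1 or 5'N-12+3'N-3","MNP",68,3
771.29,"3'N-14","MNP",71,4
1543.59,"3'N-14","MNP",69,3
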