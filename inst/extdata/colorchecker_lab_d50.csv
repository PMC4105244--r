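swatch_id,name,L,a,b
1,dark skin,37.99,13.56,14.06
2,light skin,65.71,18.13,17.81
3,blue sky,49.93,-4.88,-21.93
4,foliage,43.14,-13.10,21.91
5,blue flower,55.11,8.84,-25.40
6,bluish green,70.72,-33.40,-0.20
7,orange,62.66,36.07,57.10
8,purplish blue,40.02,10.41,-45.96
9,moderate red,51.12,48.24,16.25
10,purple,30.33,22.98,-21.59
11,yellow green,72.53,-23.71,57.26
12,orange yellow,71.94,19.36,67.86
13,blue,28.78,14.18,-50.30
14,green,55.26,-38.34,31.37
15,red,42.10,53.38,28.19
16,yellow,81.73,4.04,79.82
17,magenta,51.94,49.99,-14.57
18,cyan,51.04,-28.63,-28.64
19,white 9.5,96.54,-0.43,1.19
20,neutral 8,81.26,-0.64,-0.34
21,neutral 6.5,66.77,-0.73,-0.50
22,neutral 5,50.87,-0.15,-0.27
23,neutral 3.5,35.66,-0.42,-1.23
24,black 2,20.46,-0.08,-0.97
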