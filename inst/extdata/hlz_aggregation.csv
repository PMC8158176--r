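"base_id","base_name","agg_id","agg_name"
1,"polar desert",1,"polar desert"
2,"subpolar dry tundra",2,"tundra"
3,"subpolar moist tundra",2,"tundra"
4,"subpolar wet tundra",2,"tundra"
5,"subpolar rain tundra",2,"tundra"
6,"boreal desert",3,"boreal desert"
7,"boreal dry scrub",3,"boreal desert"
8,"boreal moist forest",4,"boreal forest"
9,"boreal wet forest",4,"boreal forest"
10,"boreal rain forest",4,"boreal forest"
11,"cool temperate desert",5,"temperate desert"
12,"cool temperate desert scrub",5,"temperate desert"
13,"cool temperate steppe",6,"temperate steppe"
14,"cool temperate moist forest",7,"temperate forest"
15,"cool temperate wet forest",7,"temperate forest"
16,"cool temperate rain forest",7,"temperate forest"
17,"warm temperate desert",5,"temperate desert"
18,"warm temperate desert scrub",5,"temperate desert"
19,"warm temperate thorn steppe",6,"temperate steppe"
20,"warm temperate dry forest",7,"temperate forest"
21,"warm temperate moist forest",7,"temperate forest"
22,"warm temperate wet forest",7,"temperate forest"
23,"warm temperate rain forest",7,"temperate forest"
24,"subtropical desert",8,"subtropical desert"
25,"subtropical desert scrub",8,"subtropical desert"
26,"subtropical thorn woodland",9,"subtropical dry forest"
27,"subtropical dry forest",9,"subtropical dry forest"
28,"subtropical moist forest",10,"subtropical moist forest"
29,"subtropical wet forest",10,"subtropical moist forest"
30,"subtropical rain forest",10,"subtropical moist forest"
31,"tropical desert",11,"tropical desert"
32,"tropical desert scrub",11,"tropical desert"
33,"tropical thorn woodland",12,"tropical dry forest"
34,"tropical very dry forest",12,"tropical dry forest"
35,"tropical dry forest",12,"tropical dry forest"
36,"tropical moist forest",13,"tropical moist forest"
37,"tropical wet forest",13,"tropical moist forest"
38,"tropical rain forest",13,"tropical moist forest"
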