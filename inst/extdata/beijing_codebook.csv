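code,label,category
1,Speed of escalator change,escalator
2,Handrail poor electrical isolation,escalator
3,Handrails are not synchronized with the escalator,escalator
4,Insufficient height between escalator and the Billboard above,escalator
5,Emergency stops,escalator
6,Unexpected reverse,escalator
7,Shake,escalator
8,Water absorbing blanket bulge,maintenance
9,The exposure of damaged part of escalator,maintenance
10,The camouflage door under the escalator opens,maintenance
11,Escalator floor plate bulges,maintenance
12,Water on floor or steps,environment
13,Object or riders falling or rolling down,environment
14,Too crowded,environment
15,Running or walking on the escalator,rider_task_driven
16,"Concentrated on mobile phones, newspapers in hand",rider_task_driven
17,With children/attending to children,rider_task_driven
18,Taking care for fellow traveler,rider_task_driven
19,Carrying wheelchair or trolley or bicycle,rider_task_driven
20,Dropping the baby out of stroller/arm,rider_task_driven
21,Carrying bulk items (luggage),rider_task_driven
22,Dropping luggage,rider_task_driven
23,Cannot lift the luggage,rider_task_driven
24,Playing on the escalator,rider_task_driven
25,Quarrels with others,rider_task_driven
26,Looking back,rider_task_driven
27,Accompanying riders,rider_task_driven
28,Help the falling riders,rider_task_driven
29,Stop luggage falling,rider_task_driven
30,Pick up the dropped item,rider_improper_riding
31,Wearing improper outfit,rider_improper_riding
32,Drop the clothing items,rider_improper_riding
33,Stepping off the escalator,rider_improper_riding
34,Step on edges of escalator steps,rider_improper_riding
35,Not holding the handrail,rider_improper_riding
36,Not standing still,rider_improper_riding
37,Fainting/black out,rider_bad_health
38,"Use of personal items on the escalator (e.g., pushchair, crutch)",rider_bad_health
39,Drunk,rider_bad_health
40,Old people have difficulty in moving,rider_bad_health
41,Pregnancy,rider_bad_health
42,Small kids unbalanced,rider_bad_health
43,Lack of lower body mobility in older/unhealthy people,rider_bad_health
44,Poor eyesight,rider_bad_health
45,Disabled,rider_bad_health
46,Bad health condition,rider_bad_health
47,Being struck/hit by luggage,rider_last_passive
48,Being knocked over by riders,rider_last_passive
49,Crushed by riders ahead or behind,rider_last_passive
50,Cannot hold the handrail,rider_last_passive
51,Cannot stand still,rider_last_passive
52,Loss of balance,rider_last_passive
53,Slipped over,rider_last_passive
54,Tripped over,rider_last_passive
55,Entrapment of outfit,rider_last_passive
56,Being pulled out of balance by suitcase,rider_last_passive
57,Being pulled out of balance by falling riders,rider_last_passive
58,Being Knocked over/hit by the part of escalator,rider_last_passive
59,Got electrocution from escalator,rider_last_passive
60,Scared,rider_last_passive
61,Sprained the ankle,rider_last_passive
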