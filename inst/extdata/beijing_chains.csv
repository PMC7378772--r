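case_id,chain
1,27→36→52→13→47→57
2,27→36→52→13→47→57
3,27→36→52→13→48→57
4,27→36→52→13→49→57
5,42→52→13→17→49→57
6,21→22→56→13→49
7,17→39→36→52→49
8,21→29→23→56→52
9,37→21→22→13→28→57
10,38→35→36→13→28→57
11,21→23→52→13→28→57
12,21→29→52→13→28→57
13,17→35→52→13→28→57
14,17→35→52→13→28→57
15,21→35→52→13→28→57
16,17→35→52→13→47
17,17→40→52→13→49
18,17→42→52→13→49
19,21→23→56→13→49
20,21→23→56→13→49
21,21→23→56→13→49
22,21→23→56→13→49
23,21→29→56→13→49
24,21→29→56→13→49
25,21→29→56→13→49
26,21→22→13→17→49
27,39→37→13→17→49
28,17→40→52→20→49
29,17→40→52→20→49
30,17→40→52→20→52
31,17→42→21→23→52
32,21→29→40→23→56
33,21→29→40→23→56
34,36→52→13→28→56
35,36→52→13→28→57
36,36→52→13→28→57
37,21→35→52→28→57
38,31→32→30→35→57
39,21→22→13→47→57
40,21→22→13→47
41,21→22→13→47
42,21→22→13→47
43,21→22→13→47
44,21→22→13→47
45,21→22→13→47
46,21→22→13→47
47,21→29→13→47
48,21→29→13→47
49,21→29→13→47
50,21→29→13→47
51,35→52→13→48
52,35→52→13→48
53,36→52→13→48
54,36→52→13→48
55,36→52→13→48
56,36→52→13→48
57,36→52→13→48
58,17→40→52→48
59,21→29→13→49
60,21→29→13→49
61,19→34→13→49
62,19→34→13→49
63,17→36→13→49
64,35→36→13→49
65,40→36→13→49
66,35→52→13→49
67,35→52→13→49
68,35→52→13→49
69,35→52→13→49
70,35→52→13→49
71,35→52→13→49
72,35→52→13→49
73,35→52→13→49
74,35→52→13→49
75,35→52→13→49
76,36→52→13→49
77,36→52→13→49
78,36→52→13→49
79,36→52→13→49
80,36→52→13→49
81,36→52→13→49
82,36→52→13→49
83,36→52→13→49
84,36→52→13→49
85,36→52→13→49
86,36→52→13→49
87,36→52→13→49
88,36→52→13→49
89,36→52→13→49
90,36→52→13→49
91,36→52→13→49
92,36→52→13→49
93,36→52→13→49
94,36→52→13→49
95,36→52→13→49
96,36→52→13→49
97,36→52→13→49
98,36→52→13→49
99,36→52→13→49
100,36→52→13→49
101,36→52→13→49
102,36→52→13→49
103,36→52→13→49
104,36→52→13→49
105,36→52→13→49
106,36→52→13→49
107,36→52→13→49
108,36→52→13→49
109,36→52→13→49
110,36→52→13→49
111,36→52→13→49
112,40→52→28→49
113,13→21→52→49
114,21→35→52→49
115,21→35→52→49
116,21→35→52→49
117,21→35→52→49
118,21→35→52→49
119,17→42→52→49
120,17→36→20→52
121,38→40→21→52
122,21→25→26→52
123,40→13→28→52
124,36→52→28→52
125,19→35→29→52
126,15→25→33→52
127,14→21→35→52
128,14→21→35→52
129,33→21→35→52
130,38→21→35→52
131,45→21→35→52
132,21→23→35→52
133,21→23→35→52
134,21→23→35→52
135,21→23→35→52
136,21→23→35→52
137,40→27→35→52
138,13→28→35→52
139,13→28→35→52
140,21→29→35→52
141,21→40→35→52
142,43→17→36→52
143,21→35→40→52
144,21→35→40→52
145,21→35→40→52
146,21→35→40→52
147,21→35→40→52
148,17→40→42→52
149,14→51→50→52
150,14→51→50→52
151,14→51→50→52
152,14→51→50→52
153,14→51→50→52
154,14→51→50→52
155,14→51→50→52
156,14→51→50→52
157,21→22→13→56
158,21→29→13→56
159,21→29→13→56
160,21→29→13→56
161,21→29→13→56
162,21→40→23→56
163,21→40→29→56
164,21→23→35→56
165,21→23→35→56
166,21→29→40→56
167,21→29→40→56
168,40→36→13→57
169,40→36→13→57
170,40→36→13→57
171,36→52→13→57
172,36→52→13→57
173,36→52→28→57
174,40→52→28→57
175,40→52→28→57
176,40→52→28→57
177,40→52→28→57
178,40→52→28→57
179,40→52→28→57
180,40→27→36→57
181,1→46→61→60
182,17→52→20
183,40→35→36
185,21→13→47
186,21→13→47
187,21→13→47
188,36→52→49
189,42→17→52
190,42→17→52
191,42→17→52
192,35→21→52
193,38→21→52
194,17→24→52
195,21→29→52
196,21→29→52
197,21→29→52
198,15→33→52
199,15→33→52
200,16→33→52
201,21→33→52
202,21→35→52
203,17→35→52
204,17→35→52
205,17→35→52
206,17→35→52
207,17→35→52
208,17→35→52
209,17→35→52
210,17→35→52
211,17→35→52
212,17→35→52
213,18→35→52
214,19→35→52
215,21→35→52
216,21→35→52
217,21→35→52
218,21→35→52
219,21→35→52
220,21→35→52
221,21→35→52
222,21→35→52
223,21→35→52
224,21→35→52
225,21→35→52
226,21→35→52
227,21→35→52
228,21→35→52
229,21→35→52
230,21→35→52
231,21→35→52
232,21→35→52
233,21→35→52
234,21→35→52
235,21→35→52
236,21→35→52
237,21→35→52
238,21→35→52
240,21→35→52
241,21→35→52
242,21→35→52
243,21→35→52
244,21→35→52
245,21→35→52
246,21→35→52
247,21→35→52
248,21→35→52
249,21→35→52
250,21→35→52
251,21→35→52
252,21→35→52
253,21→35→52
254,21→35→52
255,21→35→52
256,21→35→52
257,21→35→52
258,21→35→52
259,21→35→52
260,21→35→52
261,21→35→52
262,21→35→52
263,21→35→52
264,21→35→52
265,21→35→52
266,21→35→52
267,21→35→52
268,21→35→52
269,21→35→52
270,24→35→52
271,38→35→52
272,40→35→52
273,38→36→52
274,40→36→52
275,40→36→52
276,40→36→52
277,40→36→52
278,40→36→52
279,40→36→52
280,40→36→52
281,40→36→52
282,40→36→52
283,42→36→52
284,43→36→52
285,43→36→52
286,16→39→52
287,21→40→52
288,38→43→52
289,38→43→52
290,1→46→52
291,41→53→52
292,33→53→52
293,31→55→52
294,31→55→52
295,21→61→52
296,33→61→52
297,12→8→54
298,19→13→56
299,21→23→56
300,21→23→56
301,21→23→56
302,21→23→56
303,21→23→56
304,21→23→56
305,21→23→56
306,21→23→56
307,21→23→56
308,21→23→56
309,21→23→56
310,21→23→56
311,21→23→56
312,21→23→56
313,21→23→56
314,21→29→56
315,21→29→56
316,21→29→56
317,21→29→56
318,21→29→56
319,21→29→56
320,21→29→56
321,21→29→56
322,21→29→56
323,27→35→57
324,27→35→57
325,1→41→60
326,1→46→60
327,1→46→60
x1,21→35→52
x2,1→46→60
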