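locus_id	sample	spectrum
NR21	tumor	19:1,20:2,21:7,22:19,23:30,24:32,25:30,26:17,27:16,28:18,29:12,30:9,31:4,32:2,33:1
BAT26	tumor	25:21,26:86,27:46,28:37,29:10
NR27	tumor	14:3,15:9,16:27,17:29,18:53,19:39,20:29,21:10,22:1
BAT25	tumor	19:4,20:15,21:17,22:12,23:10,24:13,25:10,26:22,27:22,28:23,29:18,30:21,31:9,32:4
NR24	tumor	19:2,20:13,21:25,22:7,23:4,29:2,30:24,31:70,32:43,33:8,34:2
NR22	tumor	12:3,13:9,14:37,15:57,16:47,17:26,18:17,19:4
MONO27	tumor	13:6,14:6,15:17,16:29,17:30,18:39,19:31,20:26,21:9,22:5,23:1,24:1
MS1	tumor	19:4,20:7,21:11,22:15,23:30,24:39,25:37,26:32,27:14,28:9,29:2
MS4	tumor	15:3,16:10,17:35,18:58,19:46,20:29,21:10,22:5,23:4
MS5	tumor	8:3,9:20,10:18,11:1,15:2,16:3,17:6,18:28,19:37,20:40,21:25,22:11,23:5,24:1
MS8	tumor	12:1,13:1,14:2,15:11,16:25,17:37,18:44,19:37,20:27,21:12,22:1,23:2
MS9	tumor	10:3,11:6,12:4,13:10,14:13,15:24,16:21,17:33,18:22,19:38,20:21,21:4,22:1
MS10	tumor	18:2,19:6,20:5,21:13,22:27,23:38,24:41,25:31,26:21,27:10,28:3,29:2,30:1
MS12	tumor	12:1,13:63,14:117,15:19
MS15	tumor	23:4,24:21,25:26,26:18,27:2,28:6,29:7,30:15,31:32,32:30,33:20,34:15,35:2,36:1,37:1
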