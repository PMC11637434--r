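locus_id	sample	spectrum
NR21	normal	14:2,15:4,16:6,17:14,18:14,19:30,20:32,21:29,22:31,23:20,24:8,25:8,27:2
BAT26	normal	19:1,20:28,21:102,22:66,23:3
NR27	normal	14:3,15:10,16:29,17:33,18:52,19:45,20:21,21:6,22:1
BAT25	normal	18:4,19:13,20:27,21:55,22:60,23:31,24:10
NR24	normal	19:2,20:7,21:13,22:22,23:31,24:35,25:31,26:19,27:17,28:12,29:8,30:2,31:1
NR22	normal	11:3,12:3,13:14,14:37,15:53,16:50,17:27,18:11,19:2
MONO27	normal	13:2,14:9,15:10,16:27,17:35,18:27,19:31,20:27,21:18,22:7,23:6,25:1
MS1	normal	18:2,19:2,20:4,21:6,22:21,23:36,24:37,25:33,26:39,27:13,28:6,29:1
MS4	normal	19:2,20:2,21:1,22:23,23:35,24:31,25:36,26:32,27:14,28:15,29:5,30:3,31:1
MS5	normal	9:1,10:3,11:6,12:25,13:49,14:56,15:41,16:15,17:4
MS8	normal	14:5,15:8,16:22,17:41,18:36,19:37,20:27,21:20,22:4
MS9	normal	18:10,19:116,20:72,21:2
MS10	normal	17:1,18:2,19:2,20:5,21:17,22:31,23:31,24:34,25:31,26:26,27:15,28:3,29:2
MS12	normal	13:53,14:134,15:13
MS15	normal	22:2,23:12,24:53,25:83,26:44,27:6
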