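pen_id,age_level,animal_a,animal_b,start_time,duration_s,standoff
w01,weaned,p1,p4,1:12:03:12,14,0
w01,weaned,p2,p5,1:12:10:41,8,0
w01,weaned,p1,p4,1:12:55:02,31,0
w01,weaned,p4,p1,1:13:22:47,6,0
w01,weaned,p3,p6,1:14:01:30,22,1
w01,weaned,p5,p2,1:15:44:19,9,0
w01,weaned,p1,p7,1:16:12:08,45,0
w01,weaned,p6,p3,1:17:30:55,12,0
w01,weaned,p2,p8,2:07:15:33,19,0
w01,weaned,p7,p4,2:08:40:06,7,1
w01,weaned,p1,p2,2:10:05:58,28,0
w01,weaned,p8,p5,2:13:27:14,11,0
w01,weaned,p4,p6,2:16:50:40,16,0
w01,weaned,p3,p1,2:17:32:21,5,0
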