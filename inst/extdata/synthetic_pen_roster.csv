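pen_id,age_level,animal_id
w01,weaned,p1
w01,weaned,p2
w01,weaned,p3
w01,weaned,p4
w01,weaned,p5
w01,weaned,p6
w01,weaned,p7
w01,weaned,p8
w01,weaned,p9
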