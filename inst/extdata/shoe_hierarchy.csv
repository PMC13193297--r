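position,task_id,label
1,look,look at shoe
2,approach,stand within arms reach of shoe
3,touch_pencil,touch shoe with a pencil
4,touch_finger,touch shoe with one fingertip
5,touch_hand,place whole hand on shoe
6,hold,hold shoe with both hands
7,hold_lap,hold shoe in lap for the task interval
8,touch_arm,touch shoe to forearm
9,touch_neck,touch shoe to neck
10,touch_face,touch shoe to face
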