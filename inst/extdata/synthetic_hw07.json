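{"id":"hw07","width":6,"height":6,"start":{"row":5,"col":0,"heading":"N"},"goal":{"row":0,"col":5},"walls":[[[0,2],[1,2]],[[0,3],[1,3]],[[1,0],[2,0]],[[2,4],[3,4]],[[3,0],[4,0]],[[3,1],[3,2]],[[4,0],[4,1]],[[4,2],[5,2]]]}
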