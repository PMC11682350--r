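label,group,correct,incorrect
Chamomile,Floral,10,5
Citrus A.B.,Floral,11,4
Cedarwood,Sweet,12,7
Origanum,Sweet,13,6
Cedarwood,Fresh,11,8
Origanum,Fresh,11,8
Chamomile,Woody,7,8
Citrus A.B.,Woody,6,9
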