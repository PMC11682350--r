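label,group,correct,incorrect
Chamomile,Floral,12,3
Citrus A.B.,Floral,13,2
Cedarwood,Sweet,12,3
Origanum,Sweet,11,4
Cedarwood,Fresh,9,6
Origanum,Fresh,13,2
Chamomile,Woody,13,2
Citrus A.B.,Woody,9,6
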