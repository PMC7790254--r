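"prototype","neuroticism","extraversion","openness","agreeableness","conscientiousness"
"resilient",-0.6,0.6,0.6,0.6,0.6
"overcontroller",0.6,-0.6,-0.6,0,0
"undercontroller",0.15,-0.15,-0.15,-0.6,-0.6
"reserved",-0.3,-0.6,-0.6,0.6,0.6
"vulnerable-resilient",0.6,0.6,0.6,0.6,0.6
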