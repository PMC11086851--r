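"participant_id","vas","odi","tsk","pcs","pseq","csq","sbt"
"P001",62,44,38,7,35,35,3
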