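{"match_id":"toy-1","team":"A","period":1,"time_s":12.5,"duration_s":2.4,"x":61.3,"y":38.2,"event_type":"pass"}
{"match_id":"toy-1","team":"B","period":2,"time_s":340,"duration_s":3.1,"x":95,"y":12.75,"event_type":"carry"}
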