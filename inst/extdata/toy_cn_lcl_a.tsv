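# synthetic toy bipartite network (code-built transcription, pinned by tests)
# CN/LCL demo, variant a: CN(u,v) = 6, LCL(u,v) = 5
# columns: left_label<TAB>right_label
u	v1
u	v2
u	v3
u1	v
u2	v
u3	v
u1	v1
u1	v2
u2	v2
u2	v3
u3	v3
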