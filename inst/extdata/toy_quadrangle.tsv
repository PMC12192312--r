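# synthetic toy bipartite network (code-built transcription, pinned by tests)
# hub quadrangle demo: NeiBLP worked example for the pair (u, v)
# columns: left_label<TAB>right_label
u	s
t1	v
t2	v
t3	v
t4	v
t5	v
t6	v
t7	v
t1	s
t2	s
t3	s
t4	s
t5	s
t6	s
t7	s
w1	s
w2	s
w3	s
w4	s
t1	x1
t1	x2
t1	x3
t1	x4
t1	x5
t1	x6
t2	x1
t2	x2
t2	x3
t2	x4
t2	x5
t2	x6
t3	x1
t3	x2
t3	x3
t3	x4
t3	x5
t3	x6
t4	x1
t4	x2
t4	x3
t4	x4
t4	x5
t4	x6
t5	x1
t5	x2
t5	x3
t5	x4
t6	x1
t6	x2
t6	x3
t6	x4
t7	x1
t7	x2
t7	x3
t7	x4
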