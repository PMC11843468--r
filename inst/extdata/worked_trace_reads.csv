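nest_id,tag_id,time,board
N1,Q1,2022-06-20T08:00:00Z,OUTER
N1,Q1,2022-06-20T08:00:03Z,INNER
N1,Q1,2022-06-20T08:10:00Z,INNER
N1,Q1,2022-06-20T08:10:03Z,OUTER
N1,Q1,2022-06-20T08:20:00Z,OUTER
N1,Q1,2022-06-20T08:20:03Z,INNER
N1,Q1,2022-06-20T08:30:00Z,INNER
N1,Q1,2022-06-20T08:30:03Z,OUTER
N1,Q1,2022-06-20T08:40:00Z,INNER
N1,Q1,2022-06-20T08:50:00Z,INNER
N1,Q1,2022-06-20T08:50:03Z,OUTER
N1,Q1,2022-06-20T08:50:25Z,OUTER
N1,Q1,2022-06-20T08:50:28Z,INNER
N1,Q1,2022-06-20T08:51:40Z,INNER
N1,Q1,2022-06-20T09:00:00Z,INNER
N1,Q1,2022-06-20T09:00:03Z,OUTER
N1,Q1,2022-06-20T09:20:00Z,OUTER
N1,Q1,2022-06-20T09:20:03Z,INNER
N1,Q1,2022-06-20T09:30:00Z,INNER
N1,Q1,2022-06-20T09:30:03Z,OUTER
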