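pt_code	pt_name	smq_id	scope
PT900001	synthetic angioedema	90000001	narrow
PT900002	synthetic face oedema	90000001	narrow
PT900003	synthetic laryngeal oedema	90000001	narrow
PT900004	synthetic urticaria	90000001	broad
PT900005	synthetic lip swelling	90000001	broad
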