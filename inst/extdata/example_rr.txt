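# recording_id: example01
# patient_id: demo
# outcome: pre_event
0.765286 N
0.757832 N
0.772544 N
0.742483 N
0.745891 N
0.747981 N
0.752472 N
0.745661 N
0.727169 N
0.707491 N
0.720144 N
0.741751 N
0.745826 N
0.737853 N
0.748198 N
0.796749 N
0.782819 N
0.761749 N
0.744815 N
0.761814 N
0.781160 N
0.742115 N
0.711580 N
0.716490 N
0.745942 N
0.746498 N
0.741218 N
0.751863 N
0.780715 N
0.791646 N
0.788383 N
0.740765 N
0.742281 N
0.754203 N
0.731547 N
0.720429 N
0.716332 N
0.754490 N
0.738580 N
0.742953 N
0.728570 N
0.774552 N
0.763753 N
0.767076 N
0.756083 N
0.486839 V
0.990488 N
0.758098 N
0.716115 N
0.627949 V
0.804839 N
0.389992 V
1.125386 N
0.726317 N
0.767184 N
0.493369 V
1.084244 N
0.751981 N
0.752613 N
0.545943 V
0.982331 N
0.519410 V
0.455877 V
0.980203 N
0.568743 V
0.952528 N
0.711436 N
0.483306 V
1.043476 N
0.775326 N
0.763720 N
0.742218 N
0.753961 N
0.563410 V
0.951449 N
0.700075 N
0.717591 N
0.750882 N
0.749336 N
0.741532 N
0.727193 N
0.764635 N
0.799625 N
0.769769 N
0.761401 N
0.749661 N
0.775117 N
0.739453 N
0.708825 N
0.722369 N
0.724371 N
0.763610 N
0.746828 N
0.753532 N
0.754686 N
0.788168 N
0.768162 N
0.751253 N
0.735720 N
0.784097 N
0.754882 N
0.752059 N
0.708402 N
0.731710 N
0.760157 N
0.745266 N
0.744388 N
0.736251 N
0.796650 N
0.783121 N
0.753400 N
0.740980 N
0.765971 N
0.743300 N
0.719614 N
0.714033 N
0.721368 N
0.747551 N
0.767315 N
0.739019 N
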