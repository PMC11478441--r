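component	score
energy	0.180
carbohydrate	0.097
protein	0.021
total_fat	0.298
saturated_fat	0.373
mufa	-0.009
pufa	-0.337
n3_fatty_acids	-0.436
n6_fatty_acids	-0.159
trans_fat	0.229
cholesterol	0.110
fiber	-0.663
alcohol	-0.278
vitamin_a	-0.401
beta_carotene	-0.584
thiamin	-0.098
riboflavin	-0.068
niacin	-0.246
vitamin_b6	-0.365
folate	-0.190
vitamin_b12	0.106
vitamin_c	-0.424
vitamin_d	-0.446
vitamin_e	-0.419
iron	0.032
magnesium	-0.484
zinc	-0.313
selenium	-0.191
caffeine	-0.110
tea	-0.536
flavan3ols	-0.415
flavones	-0.616
flavonols	-0.467
flavonones	-0.250
anthocyanidins	-0.131
isoflavones	-0.593
onion	-0.301
pepper	-0.131
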