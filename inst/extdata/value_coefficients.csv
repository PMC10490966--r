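function_code,category,forestland,cultivated,built_up,grassland,barren,water
WS,provisioning,8,,,,,2117
FP,provisioning,32,187.56,,117.45,,41
RM,provisioning,51.24,,,,,
GR,provisioning,41,,,,,
Gr,regulatory,13.68,,,7,,
Cr,regulatory,223,,,,,
Dr,regulatory,5,,,,,
Hr,regulatory,6,,,3,,5445
EC,regulatory,245,,,29,,
BC,regulatory,,24,,23,,
WT,regulatory,136,,,87,,431.5
NC,supporting,184.4,,,,,
SF,supporting,10,,,1,,
Ha,supporting,17.3,,,,,
Po,supporting,7.27,14,,25,,
Re,recreation_culture,4.8,,,0.8,,69
Cu,recreation_culture,2,,,,,
TOTAL,,986.69,225.56,0,293.25,0,8103.5
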