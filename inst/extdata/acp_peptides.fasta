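>lasio_iii amidated Lasioglossin LL-III (hymenopteran venom)
VNWKKILGKIIKVVK
>macro1 amidated Macropin 1 (hymenopteran venom)
GFGMALKLLKKVL
>tempo_la amidated Temporin-La (anuran skin)
LLRHVVKILEKYL
>fk16 amidated FK-16 (cathelicidin fragment)
FKRIVQRIKDFLRNLV
>ll37 amidated LL-37 (human cathelicidin)
LLGDFFRKSKEKIGKEFKRIVQRIKDFLRNLVPRTES
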