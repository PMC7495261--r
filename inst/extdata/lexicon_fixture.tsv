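word	value
素晴らしい	1
安心	0.1
便利	0.2
楽しい	0.3
嬉しい	0.4
良い	0.5
素敵	0.6
健康	0.7
幸せ	0.8
感動	0.9
元気	0.01
静か	0.02
明るい	0.03
温かい	0.04
丁寧	0.05
親切	0.06
清潔	0.07
爽やか	0.08
豊か	0.09
最悪	-1
不安	-0.1
心配	-0.2
悪い	-0.3
怖い	-0.4
危険	-0.5
汚染	-0.6
恐怖	-0.7
絶望	-0.8
悲惨	-0.9
眠い	-0.01
退屈	-0.02
曇り	-0.03
騒音	-0.04
疲れる	-0.05
残念	-0.06
迷惑	-0.07
苦情	-0.08
違反	-0.09
放射能	-0.598318
放射線	-0.560393
放射性	-0.178744
優れる	1
美味しい	0.89
未来	0.45
晴れ	0.35
子供	0.28
学校	0.12
普通	-0.16
雨	-0.27
政府	-0.33
避難	-0.71
地震	-0.82
津波	-0.88
事故	-0.95
検査	-0.12
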