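prefecture	population
Hokkaido	5506419
Aomori	1373339
Iwate	1330147
Miyagi	2348165
Akita	1085997
Yamagata	1168924
Fukushima	2029064
Ibaraki	2969770
Tochigi	2007683
Gunma	2008068
Saitama	7194556
Chiba	6216289
Tokyo	13159388
Kanagawa	9048331
Niigata	2374450
Toyama	1093247
Ishikawa	1169788
Fukui	806314
Yamanashi	863075
Nagano	2152449
Gifu	2080773
Shizuoka	3765007
Aichi	7410719
Mie	1854724
Shiga	1410777
Kyoto	2636092
Osaka	8865245
Hyogo	5588133
Nara	1400728
Wakayama	1002198
Tottori	588667
Shimane	717397
Okayama	1945276
Hiroshima	2860750
Yamaguchi	1451338
Tokushima	785491
Kagawa	995842
Ehime	1431493
Kochi	764456
Fukuoka	5071968
Saga	849788
Nagasaki	1426779
Kumamoto	1817426
Oita	1196529
Miyazaki	1135233
Kagoshima	1706242
Okinawa	1392818
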