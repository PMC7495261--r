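prefix	prefecture
011	Hokkaido
017	Aomori
019	Iwate
022	Miyagi
018	Akita
023	Yamagata
024	Fukushima
0246	Fukushima
029	Ibaraki
028	Tochigi
027	Gunma
048	Saitama
043	Chiba
03	Tokyo
045	Kanagawa
025	Niigata
0764	Toyama
0762	Ishikawa
0776	Fukui
055	Yamanashi
026	Nagano
058	Gifu
054	Shizuoka
052	Aichi
059	Mie
077	Shiga
075	Kyoto
06	Osaka
078	Hyogo
0742	Nara
073	Wakayama
0857	Tottori
0852	Shimane
086	Okayama
082	Hiroshima
083	Yamaguchi
0886	Tokushima
087	Kagawa
089	Ehime
0888	Kochi
092	Fukuoka
0952	Saga
095	Nagasaki
096	Kumamoto
097	Oita
0985	Miyazaki
099	Kagoshima
098	Okinawa
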