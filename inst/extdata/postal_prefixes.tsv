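prefix	prefecture
060	Hokkaido
030	Aomori
020	Iwate
980	Miyagi
010	Akita
990	Yamagata
960	Fukushima
963	Fukushima
970	Fukushima
310	Ibaraki
320	Tochigi
371	Gunma
330	Saitama
260	Chiba
100	Tokyo
150	Tokyo
220	Kanagawa
231	Kanagawa
950	Niigata
930	Toyama
920	Ishikawa
910	Fukui
400	Yamanashi
380	Nagano
500	Gifu
420	Shizuoka
460	Aichi
514	Mie
520	Shiga
600	Kyoto
530	Osaka
650	Hyogo
630	Nara
640	Wakayama
680	Tottori
690	Shimane
700	Okayama
730	Hiroshima
753	Yamaguchi
770	Tokushima
760	Kagawa
790	Ehime
780	Kochi
810	Fukuoka
840	Saga
850	Nagasaki
860	Kumamoto
870	Oita
880	Miyazaki
890	Kagoshima
900	Okinawa
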