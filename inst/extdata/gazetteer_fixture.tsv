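word	prefecture
北海道	Hokkaido
札幌	Hokkaido
青森	Aomori
岩手	Iwate
盛岡	Iwate
宮城	Miyagi
仙台	Miyagi
秋田	Akita
山形	Yamagata
福島	Fukushima
福島市	Fukushima
福島県	Fukushima
いわき	Fukushima
郡山	Fukushima
茨城	Ibaraki
水戸	Ibaraki
栃木	Tochigi
宇都宮	Tochigi
群馬	Gunma
前橋	Gunma
埼玉	Saitama
千葉	Chiba
東京	Tokyo
東京都	Tokyo
新宿	Tokyo
渋谷	Tokyo
世田谷	Tokyo
神奈川	Kanagawa
横浜	Kanagawa
新潟	Niigata
富山	Toyama
石川	Ishikawa
金沢	Ishikawa
福井	Fukui
山梨	Yamanashi
甲府	Yamanashi
長野	Nagano
岐阜	Gifu
静岡	Shizuoka
愛知	Aichi
名古屋	Aichi
三重	Mie
滋賀	Shiga
京都	Kyoto
大阪	Osaka
兵庫	Hyogo
神戸	Hyogo
奈良	Nara
和歌山	Wakayama
鳥取	Tottori
島根	Shimane
松江	Shimane
岡山	Okayama
広島	Hiroshima
山口	Yamaguchi
徳島	Tokushima
香川	Kagawa
高松	Kagawa
愛媛	Ehime
松山	Ehime
高知	Kochi
福岡	Fukuoka
佐賀	Saga
長崎	Nagasaki
熊本	Kumamoto
大分	Oita
宮崎	Miyazaki
鹿児島	Kagoshima
沖縄	Okinawa
那覇	Okinawa
チェルノブイリ	Other
スリーマイル島	Other
丁目	Other
番地	Other
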