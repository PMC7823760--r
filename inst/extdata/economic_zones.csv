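region,zone
Beijing,Beijing-Tianjin-Hebei
Tianjin,Beijing-Tianjin-Hebei
Hebei,Beijing-Tianjin-Hebei
Liaoning,Three Northeast Provinces
Jilin,Three Northeast Provinces
Heilongjiang,Three Northeast Provinces
Shanghai,Yangtze River Delta
Jiangsu,Yangtze River Delta
Zhejiang,Yangtze River Delta
Shandong,East China Coastal Area
Fujian,East China Coastal Area
Hainan,East China Coastal Area
Henan,Central Plains Region
Shanxi,Central Plains Region
Anhui,Central Plains Region
Hubei,Central Plains Region
Hunan,Central Plains Region
Jiangxi,Central Plains Region
Guangdong,Pearl River Delta
Guangxi,Pearl River Delta
Sichuan,Southwest China
Chongqing,Southwest China
Guizhou,Southwest China
Yunnan,Southwest China
Shaanxi,Five Northwest Provinces
Gansu,Five Northwest Provinces
Qinghai,Five Northwest Provinces
Ningxia,Five Northwest Provinces
Xinjiang,Five Northwest Provinces
Inner Mongolia,Five Northwest Provinces
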