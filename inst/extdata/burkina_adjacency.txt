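# Region adjacency for the 13 administrative regions of Burkina Faso.
# One undirected edge per line, tab-separated. Transcribed by hand from the
# national administrative map; borders shorter than ~5 km were judgement calls.
Boucle du Mouhoun	Nord
Boucle du Mouhoun	Centre-Ouest
Boucle du Mouhoun	Hauts Bassins
Boucle du Mouhoun	Sud-Ouest
Cascades	Hauts Bassins
Cascades	Sud-Ouest
Centre	Plateau Central
Centre	Centre-Ouest
Centre	Centre-Sud
Centre-Est	Centre-Sud
Centre-Est	Plateau Central
Centre-Est	Est
Centre-Nord	Sahel
Centre-Nord	Nord
Centre-Nord	Plateau Central
Centre-Nord	Est
Centre-Ouest	Centre-Sud
Centre-Ouest	Sud-Ouest
Centre-Ouest	Nord
Est	Sahel
Hauts Bassins	Sud-Ouest
Nord	Sahel
Nord	Plateau Central
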