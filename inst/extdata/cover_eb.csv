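species,observed,blind,calibrated
Abies balsamea,0.00,0.14,0.01
Acer pensylvanicum,0.07,0.01,0.02
Acer rubrum,0.02,0.14,0.02
Acer saccharum,0.03,0.00,0.01
Aralia nudicaulis,0.03,0.00,0.04
Arisaema triphyllum,0.00,0.00,0.00
Betula alleghaniensis,0.13,0.14,0.12
Clintonia borealis,,,
Coptis trifolia,0.01,0.00,0.00
Cornus alternifolia,0.00,0.00,0.00
Cornus canadensis,0.01,0.03,0.02
Dennstaedtia punctilobula,0.00,0.02,0.02
Diervilla lonicera,0.00,0.00,0.00
Dryopteris campyloptera,0.21,0.00,0.15
Dryopteris intermedia,,,
Fagus grandifolia,0.25,0.01,0.22
Fragaria virginiana,0.00,0.01,0.01
Fraxinus americana,0.00,0.01,0.01
Gymnocarpium dryopteris,0.00,0.00,0.00
Huperzia lucidula,,,
Lonicera canadensis,0.00,0.00,0.00
Maianthemum canadense,0.02,0.00,0.00
Maianthemum racemosum,,,
Medeola virginiana,0.00,0.00,0.00
Monotropa uniflora,,,
Oclemena acuminata,,,
Osmunda claytoniana,0.05,0.00,0.03
Oxalis montana,,,
Phegopteris connectilis,0.00,0.00,0.00
Picea rubens,0.07,0.10,0.08
Polygonatum pubescens,,,
Polygonum convolvulus,0.00,0.00,0.00
Polystichum acrostichoides,,,
Prunus serotina,0.00,0.00,0.00
Quercus rubra,,,
Ribes glandulosum,0.00,0.00,0.01
Sorbus americana,0.00,0.10,0.01
Thelypteris noveboracensis,0.00,0.05,0.00
Trientalis borealis,0.02,0.00,0.00
Trillium spp,,,
Tsuga canadensis,0.02,0.14,0.01
Uvularia sessilifolia,0.05,0.00,0.01
Viburnum acerifolium,0.00,0.00,0.00
Viburnum lantanoides,0.00,0.12,0.02
Viola rotundifolia,,,
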