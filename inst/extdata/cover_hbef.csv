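species,observed,blind,calibrated
Abies balsamea,,,
Acer pensylvanicum,0.01,0.04,0.05
Acer rubrum,,,
Acer saccharum,0.01,0.00,0.02
Aralia nudicaulis,,,
Arisaema triphyllum,,,
Betula alleghaniensis,0.02,0.00,0.03
Clintonia borealis,0.04,0.04,0.04
Coptis trifolia,,,
Cornus alternifolia,,,
Cornus canadensis,,,
Dennstaedtia punctilobula,0.00,0.68,0.03
Diervilla lonicera,,,
Dryopteris campyloptera,,,
Dryopteris intermedia,0.32,0.00,0.33
Fagus grandifolia,0.07,0.00,0.05
Fragaria virginiana,,,
Fraxinus americana,,,
Gymnocarpium dryopteris,,,
Huperzia lucidula,0.10,0.00,0.06
Lonicera canadensis,,,
Maianthemum canadense,0.03,0.00,0.00
Maianthemum racemosum,0.01,0.00,0.00
Medeola virginiana,0.00,0.00,0.00
Monotropa uniflora,0.00,0.00,0.00
Oclemena acuminata,0.01,0.00,0.00
Osmunda claytoniana,,,
Oxalis montana,0.02,0.00,0.01
Phegopteris connectilis,,,
Picea rubens,,,
Polygonatum pubescens,,,
Polygonum convolvulus,,,
Polystichum acrostichoides,,,
Prunus serotina,,,
Quercus rubra,,,
Ribes glandulosum,,,
Sorbus americana,,,
Thelypteris noveboracensis,,,
Trientalis borealis,0.00,0.00,0.00
Trillium spp,0.00,0.00,0.00
Tsuga canadensis,,,
Uvularia sessilifolia,0.04,0.00,0.05
Viburnum acerifolium,0.29,0.25,0.34
Viburnum lantanoides,,,
Viola rotundifolia,0.00,0.00,0.00
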