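Default level-1 reclassification schemes collapsing source legends into
the three analysis classes (1 = natural cover, 2 = anthropic use,
3 = water). The exact grouping tables used by the original national and
MapBiomas products are not published alongside their class lists, so
these files are ASSUMED defaults (hence the file names): edit them to
match the legend of your own input product before running the pipeline.

maate-style level 1 (assumed): 1 forest, 2 shrub/herbaceous vegetation,
3 agricultural land, 4 water body, 5 anthropic zone, 6 other land.
mapbiomas-style level 1 (assumed): 1 forest, 10 non-forest natural
formation, 14 farming, 22 non-vegetated area, 26 water, 27 not observed.
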