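<?xml version="1.0" encoding="UTF-8"?>
<article xmlns:xlink="http://www.w3.org/1999/xlink" article-type="research-article">
<front><journal-meta><journal-title-group><journal-title>Example Journal</journal-title></journal-title-group></journal-meta>
<article-meta><article-id pub-id-type="pmc">PMC9000001</article-id>
<title-group><article-title>An example article with accession citations</article-title></title-group>
<pub-date><year>2007</year></pub-date></article-meta></front>
<body>
<sec><title>Results</title>
<p>Hence in the present study, three templates (PDB IDs:1J4N, 1FX8 and 1RC2-B chain) were chosen for modelling. In 2008 we also consulted the PDB for related entries.</p>
<p>Sequences specifically obtained for this study have been deposited in GenBank [GenBank: EF151088&#8211;EF151123 and EF153103]. The structure <ext-link ext-link-type="pdb" xlink:href="1EWK">1EWK</ext-link> was used for comparison.</p>
</sec>
</body>
<back>
<fn-group><fn><p>Sequence data: GenBank CP000155.</p></fn></fn-group>
<ref-list><ref><mixed-citation>Smith J (2004) Methods in molecular analysis. J Mol Res 12:34-45.</mixed-citation></ref></ref-list>
</back>
</article>
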