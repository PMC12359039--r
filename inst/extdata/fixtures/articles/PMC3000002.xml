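<?xml version="1.0" encoding="UTF-8"?>
<article>
  <front>
    <journal-meta><journal-title-group><journal-title>
      Annals of Community Ecology
    </journal-title></journal-title-group>
    <publisher><publisher-name>Synthetic Press</publisher-name></publisher></journal-meta>
    <article-meta><title-group><article-title>
      A synthetic survey of gut microbial community structure
    </article-title></title-group>
    <pub-date><year>2017</year></pub-date>
    </article-meta>
  </front>
  <body>
    <sec><title>Introduction</title><p>Gut microbial communities influence host physiology, immune development, and nutrient cycling. We profiled stool specimens from adult volunteers to characterize community structure across diet groups.</p></sec>
    <sec><title>Methods</title><p>The V4 hypervariable region of the 16S rRNA gene was amplified and sequenced. Amplification used primers 515F (RCWCTGGTVAAWNRYTGACAVG) and 1193R (GAATARACCTGCGGACCAG).</p></sec>
    <sec><title>Results</title><p>Community composition differed among diet groups, and alpha diversity was higher in participants consuming fermented foods. Taxonomic shifts were concentrated in a small number of genera.</p></sec>
    <sec><title>Code availability</title><p>Analysis code and processing scripts used in this study are archived at https://github.com/lab980/analysis63.</p></sec>
  </body>
  <back>
    <sec sec-type="data-availability"><title>Data Availability</title><p>Raw sequence reads generated in this study were deposited in the NCBI Sequence Read Archive (SRA) under accession PRJNA199293 (runs including SRR4538229).</p></sec>
  </back>
</article>
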