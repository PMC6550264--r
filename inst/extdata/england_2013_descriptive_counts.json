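{
  "description": "Summary counts from a published national analysis of English hospital attendance records (secondary care, April 2013 to March 2015; 12-month follow-up per patient). Used as worked-example inputs for the package's descriptive and network arithmetic.",
  "counts": {
    "n_patients": 19682360,
    "n_interactions": 130161023,
    "n_multi_presenters": 16002415,
    "n_multi_provider_patients": 4162780,
    "n_interactions_multi": 126481078,
    "n_interactions_multi_provider": 46966969,
    "n_fragmented": 14748791
  },
  "network": {
    "n_providers": 155,
    "n_edges": 11641
  }
}
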