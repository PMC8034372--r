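Replication inputs (not shipped)
================================

The full replication of the published tarantula analysis needs three
supplementary files that are distributed with the original study and are
not redistributed here.  To run the replication checks, place them in
this directory as:

  chronogram.nwk   the fossil-dated theraphosid chronogram (Newick,
                   branch lengths in Ma, internal node labels 20-46)
  codings.tsv      taxon range codings, two tab-separated columns:
                   taxon, area letters over A-E (e.g. "AB")
  exclusions.txt   excluded ancestral area combinations, one letter
                   string per line (e.g. "BD")

With these present, the replication test fits the DEC model to the
chronogram and codings and compares the maximized log-likelihood and the
node-21 event matrix against the published values.
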