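# Bundled fixtures

All fixtures are synthetic and generated by `generate_synthetic()`; the
files here exist only so the CLI can be exercised without writing code.

- `demo_sbm.edges` — synthetic planted-partition network (two blocks of
  30 nodes, within-block edge probability 0.25, between-block 0.02,
  seed 2024; 60 nodes / 223 edges). A small stand-in with community
  structure and near-homogeneous degrees, loosely emulating the density
  regime of small social networks (a few hundred links). It does not
  reproduce heavy-tailed degrees or high clustering; see the methods
  vignette for what synthetic fixtures do and do not emulate.
- `demo.yaml` — experiment configuration for
  `linkstack experiment --config demo.yaml` (generates the same network
  from its spec rather than reading a file).

Real benchmark networks are not shipped; supply them as edge lists via
`read_edge_list()` or `--edge-list`.
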