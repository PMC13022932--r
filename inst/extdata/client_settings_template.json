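{
  "workspace_root": "/home/fl/workspace",
  "dataset_root": "/data/bids_dataset",
  "target_column": "sdmt",
  "server": "server",
  "client_name": "brussels"
}
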