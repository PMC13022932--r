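{
  "workspace_root": "/home/user/fl_workspace",
  "clients": [
    {"name": "brussels", "address": "10.0.0.2", "workspace_root": "/home/fl/workspace"},
    {"name": "greifswald", "address": "10.0.0.3", "workspace_root": "/home/fl/workspace"},
    {"name": "prague", "address": "10.0.0.4", "workspace_root": "/data/fl/workspace"}
  ],
  "model_definition": "/home/user/fl_workspace/model_definition.R",
  "plan_path": "/home/user/fl_workspace/fl_plan.json"
}
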