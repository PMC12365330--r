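{
  "description": "Column specification template for 28-attribute UCI-style thyroid screening data. Schema template only (no data): names and kinds follow the standard public thyroid attribute layout.",
  "target": "class",
  "na_tokens": ["?"],
  "columns": [
    {"name": "age", "kind": "numeric"},
    {"name": "sex", "kind": "categorical"},
    {"name": "on_thyroxine", "kind": "boolean"},
    {"name": "query_on_thyroxine", "kind": "boolean"},
    {"name": "on_antithyroid_medication", "kind": "boolean"},
    {"name": "sick", "kind": "boolean"},
    {"name": "pregnant", "kind": "boolean"},
    {"name": "thyroid_surgery", "kind": "boolean"},
    {"name": "I131_treatment", "kind": "boolean"},
    {"name": "query_hypothyroid", "kind": "boolean"},
    {"name": "query_hyperthyroid", "kind": "boolean"},
    {"name": "lithium", "kind": "boolean"},
    {"name": "goitre", "kind": "boolean"},
    {"name": "tumor", "kind": "boolean"},
    {"name": "hypopituitary", "kind": "boolean"},
    {"name": "psych", "kind": "boolean"},
    {"name": "TSH_measured", "kind": "boolean"},
    {"name": "T3_measured", "kind": "boolean"},
    {"name": "TT4_measured", "kind": "boolean"},
    {"name": "T4U_measured", "kind": "boolean"},
    {"name": "FTI_measured", "kind": "boolean"},
    {"name": "TBG_measured", "kind": "boolean"},
    {"name": "TSH", "kind": "numeric"},
    {"name": "T3", "kind": "numeric"},
    {"name": "TT4", "kind": "numeric"},
    {"name": "T4U", "kind": "numeric"},
    {"name": "FTI", "kind": "numeric"},
    {"name": "TBG", "kind": "numeric"}
  ]
}
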