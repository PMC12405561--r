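site_id,source_type,reference
S001,global_database,synthetic-source-1
S002,global_database,synthetic-source-2
S003,peer_reviewed,synthetic-source-3
S004,peer_reviewed,synthetic-source-4
S005,global_database,synthetic-source-5
S006,peer_reviewed,synthetic-source-6
S007,peer_reviewed,synthetic-source-7
S008,peer_reviewed,synthetic-source-8
S009,meta_analysis,synthetic-source-9
S010,peer_reviewed,synthetic-source-10
S011,meta_analysis,synthetic-source-11
S012,peer_reviewed,synthetic-source-12
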