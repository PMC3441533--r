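format-version: 1.2
ontology: toy

[Term]
id: GO:0000001
name: metabolic process
namespace: biological_process

[Term]
id: GO:0000002
name: carbohydrate metabolic process
namespace: biological_process
is_a: GO:0000001 ! metabolic process

[Term]
id: GO:0000003
name: glycolytic process
namespace: biological_process
is_a: GO:0000002 ! carbohydrate metabolic process

[Term]
id: GO:0000004
name: nucleus
namespace: cellular_component

[Term]
id: GO:0000005
name: obsolete widget process
namespace: biological_process
is_obsolete: true
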