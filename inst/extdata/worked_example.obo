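format-version: 1.2
ontology: mirgosim-worked-example

[Term]
id: GO:0008150
name: biological_process
namespace: biological_process

[Term]
id: GO:0032502
name: developmental process
namespace: biological_process
is_a: GO:0008150 ! biological_process

[Term]
id: GO:0048856
name: anatomical structure development
namespace: biological_process
is_a: GO:0032502 ! developmental process

[Term]
id: GO:0048731
name: system development
namespace: biological_process
is_a: GO:0048856 ! anatomical structure development

[Term]
id: GO:0072359
name: circulatory system development
namespace: biological_process
is_a: GO:0048731 ! system development

[Term]
id: GO:0048513
name: animal organ development
namespace: biological_process
is_a: GO:0048731 ! system development

[Term]
id: GO:0072358
name: cardiovascular system development
namespace: biological_process
relationship: part_of GO:0072359 ! circulatory system development
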