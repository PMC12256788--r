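format-version: 1.2
ontology: synthetic-phenotype-ontology
remark: Synthetic phenotype ontology for examples and tests. Term ids and names are invented; this is NOT the Human Phenotype Ontology.

[Term]
id: SP:0000001
name: Phenotypic abnormality

[Term]
id: SP:0000100
name: Abnormality of the nervous system
is_a: SP:0000001 ! Phenotypic abnormality

[Term]
id: SP:0000101
name: Seizure
is_a: SP:0000100 ! Abnormality of the nervous system

[Term]
id: SP:0000102
name: Focal seizure
is_a: SP:0000101 ! Seizure

[Term]
id: SP:0000103
name: Generalized tonic-clonic seizure
is_a: SP:0000101 ! Seizure

[Term]
id: SP:0000104
name: Encephalopathy
is_a: SP:0000100 ! Abnormality of the nervous system

[Term]
id: SP:0000105
name: Stroke-like episode
is_a: SP:0000100 ! Abnormality of the nervous system

[Term]
id: SP:0000106
name: Ataxia
is_a: SP:0000100 ! Abnormality of the nervous system

[Term]
id: SP:0000107
name: Cerebellar ataxia
is_a: SP:0000106 ! Ataxia

[Term]
id: SP:0000108
name: Developmental regression
is_a: SP:0000100 ! Abnormality of the nervous system

[Term]
id: SP:0000109
name: Intellectual disability
is_a: SP:0000100 ! Abnormality of the nervous system

[Term]
id: SP:0000110
name: Migraine
is_a: SP:0000100 ! Abnormality of the nervous system

[Term]
id: SP:0000111
name: Peripheral neuropathy
is_a: SP:0000100 ! Abnormality of the nervous system

[Term]
id: SP:0000112
name: Axonal neuropathy
is_a: SP:0000111 ! Peripheral neuropathy

[Term]
id: SP:0000113
name: Myoclonus
is_a: SP:0000100 ! Abnormality of the nervous system

[Term]
id: SP:0000114
name: Dystonia
is_a: SP:0000100 ! Abnormality of the nervous system

[Term]
id: SP:0000115
name: Bilateral basal ganglia lesions
is_a: SP:0000100 ! Abnormality of the nervous system

[Term]
id: SP:0000116
name: Leukoencephalopathy
is_a: SP:0000100 ! Abnormality of the nervous system

[Term]
id: SP:0000200
name: Abnormality of the musculature
is_a: SP:0000001 ! Phenotypic abnormality

[Term]
id: SP:0000201
name: Myopathy
is_a: SP:0000200 ! Abnormality of the musculature

[Term]
id: SP:0000202
name: Mitochondrial myopathy
is_a: SP:0000201 ! Myopathy

[Term]
id: SP:0000203
name: Exercise intolerance
is_a: SP:0000200 ! Abnormality of the musculature

[Term]
id: SP:0000204
name: Muscle weakness
is_a: SP:0000200 ! Abnormality of the musculature

[Term]
id: SP:0000205
name: Proximal muscle weakness
is_a: SP:0000204 ! Muscle weakness

[Term]
id: SP:0000206
name: Ptosis
is_a: SP:0000200 ! Abnormality of the musculature
is_a: SP:0000300 ! Abnormality of the eye

[Term]
id: SP:0000207
name: Ophthalmoplegia
is_a: SP:0000200 ! Abnormality of the musculature
is_a: SP:0000300 ! Abnormality of the eye

[Term]
id: SP:0000208
name: Progressive external ophthalmoplegia
is_a: SP:0000207 ! Ophthalmoplegia

[Term]
id: SP:0000209
name: Hypotonia
is_a: SP:0000200 ! Abnormality of the musculature

[Term]
id: SP:0000210
name: Rhabdomyolysis
is_a: SP:0000200 ! Abnormality of the musculature

[Term]
id: SP:0000300
name: Abnormality of the eye
is_a: SP:0000001 ! Phenotypic abnormality

[Term]
id: SP:0000301
name: Optic atrophy
is_a: SP:0000300 ! Abnormality of the eye

[Term]
id: SP:0000302
name: Visual loss
is_a: SP:0000300 ! Abnormality of the eye

[Term]
id: SP:0000303
name: Central visual loss
is_a: SP:0000302 ! Visual loss

[Term]
id: SP:0000304
name: Pigmentary retinopathy
is_a: SP:0000300 ! Abnormality of the eye

[Term]
id: SP:0000305
name: Cataract
is_a: SP:0000300 ! Abnormality of the eye

[Term]
id: SP:0000306
name: Nystagmus
is_a: SP:0000300 ! Abnormality of the eye
is_a: SP:0000100 ! Abnormality of the nervous system

[Term]
id: SP:0000400
name: Abnormality of the ear
is_a: SP:0000001 ! Phenotypic abnormality

[Term]
id: SP:0000401
name: Hearing impairment
is_a: SP:0000400 ! Abnormality of the ear

[Term]
id: SP:0000402
name: Sensorineural hearing impairment
is_a: SP:0000401 ! Hearing impairment

[Term]
id: SP:0000500
name: Abnormality of metabolism
is_a: SP:0000001 ! Phenotypic abnormality

[Term]
id: SP:0000501
name: Lactic acidosis
is_a: SP:0000500 ! Abnormality of metabolism

[Term]
id: SP:0000502
name: Diabetes mellitus
is_a: SP:0000500 ! Abnormality of metabolism

[Term]
id: SP:0000503
name: Hyperalaninemia
is_a: SP:0000500 ! Abnormality of metabolism

[Term]
id: SP:0000504
name: Ketoacidosis
is_a: SP:0000500 ! Abnormality of metabolism

[Term]
id: SP:0000600
name: Abnormality of the cardiovascular system
is_a: SP:0000001 ! Phenotypic abnormality

[Term]
id: SP:0000601
name: Cardiomyopathy
is_a: SP:0000600 ! Abnormality of the cardiovascular system

[Term]
id: SP:0000602
name: Hypertrophic cardiomyopathy
is_a: SP:0000601 ! Cardiomyopathy

[Term]
id: SP:0000603
name: Dilated cardiomyopathy
is_a: SP:0000601 ! Cardiomyopathy

[Term]
id: SP:0000604
name: Cardiac conduction abnormality
is_a: SP:0000600 ! Abnormality of the cardiovascular system

[Term]
id: SP:0000605
name: Heart block
is_a: SP:0000604 ! Cardiac conduction abnormality

[Term]
id: SP:0000700
name: Abnormality of the digestive system
is_a: SP:0000001 ! Phenotypic abnormality

[Term]
id: SP:0000701
name: Vomiting
is_a: SP:0000700 ! Abnormality of the digestive system

[Term]
id: SP:0000702
name: Intestinal pseudo-obstruction
is_a: SP:0000700 ! Abnormality of the digestive system

[Term]
id: SP:0000703
name: Dysphagia
is_a: SP:0000700 ! Abnormality of the digestive system

[Term]
id: SP:0000704
name: Hepatopathy
is_a: SP:0000700 ! Abnormality of the digestive system

[Term]
id: SP:0000800
name: Growth abnormality
is_a: SP:0000001 ! Phenotypic abnormality

[Term]
id: SP:0000801
name: Short stature
is_a: SP:0000800 ! Growth abnormality

[Term]
id: SP:0000802
name: Failure to thrive
is_a: SP:0000800 ! Growth abnormality

[Term]
id: SP:0000803
name: Fatigue
is_a: SP:0000001 ! Phenotypic abnormality

[Term]
id: SP:0000900
name: Abnormality of the kidney
is_a: SP:0000001 ! Phenotypic abnormality

[Term]
id: SP:0000901
name: Renal tubular dysfunction
is_a: SP:0000900 ! Abnormality of the kidney

[Term]
id: SP:0000998
name: obsolete Lactacidemia
is_obsolete: true
replaced_by: SP:0000501

[Term]
id: SP:0000999
name: obsolete Unspecified finding
is_obsolete: true
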