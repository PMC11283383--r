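# Editable ICD-10 code map used by the comorbidity and safety modules.
# Codes are prefixes, matched on normalized codes (uppercase, dots removed):
# "I50" matches I50, I50.0, I500, ...
#
# - comorbidity: descriptive categories for the baseline profile.
#   Cardiovascular subtypes are grouped under the `cardiovascular.` prefix;
#   the top-level cardiovascular flag is their OR (plus probabilistic
#   markers handled in code).
# - charlson: the Quan ICD-10 coding of the Charlson index, with weights.
#   `hierarchy` lists severe forms that supersede their mild counterpart.
# - safety_events: hospital discharge diagnoses defining the six
#   cardiovascular / bleeding event categories of interest.

comorbidity:
  liver_cirrhosis: [B18, K70, K71, K72, K73, K74]
  cardiovascular.disabling_stroke: [I60, I61, I62, I63, I64, G81, G82]
  cardiovascular.chronic_arterial_disease: [I70, I71, I72, I73]
  cardiovascular.heart_failure_arrhythmia_valvular:
    [I05, I06, I07, I08, I09, I34, I35, I36, I37, I42, I43, I44, I45, I46,
     I47, I48, I49, I50]
  cardiovascular.severe_hypertension: [I10, I11, I12, I13, I15]
  cardiovascular.coronary_artery_disease: [I20, I21, I22, I23, I24, I25]
  respiratory_failure: [J44, J45, J46, J47, J60, J61, J62, J63, J64, J65,
                        J66, J67, J96, E84]
  kidney_disease: [N18, N19, Z49, Z940, Z992]
  solid_tumour: [C0, C1, C2, C3, C4, C5, C6, C7, C80]

charlson:
  myocardial_infarction:
    weight: 1
    codes: [I21, I22, I252]
  congestive_heart_failure:
    weight: 1
    codes: [I099, I110, I130, I132, I255, I420, I425, I426, I427, I428,
            I429, I43, I50, P290]
  peripheral_vascular_disease:
    weight: 1
    codes: [I70, I71, I731, I738, I739, I771, I790, I792, K551, K558,
            K559, Z958, Z959]
  cerebrovascular_disease:
    weight: 1
    codes: [G45, G46, H340, I60, I61, I62, I63, I64, I65, I66, I67, I68,
            I69]
  dementia:
    weight: 1
    codes: [F00, F01, F02, F03, F051, G30, G311]
  chronic_pulmonary_disease:
    weight: 1
    codes: [I278, I279, J40, J41, J42, J43, J44, J45, J46, J47, J60, J61,
            J62, J63, J64, J65, J66, J67, J684, J701, J703]
  rheumatic_disease:
    weight: 1
    codes: [M05, M06, M315, M32, M33, M34, M351, M353, M360]
  peptic_ulcer_disease:
    weight: 1
    codes: [K25, K26, K27, K28]
  mild_liver_disease:
    weight: 1
    codes: [B18, K700, K701, K702, K703, K709, K713, K714, K715, K717,
            K73, K74, K760, K762, K763, K764, K768, K769, Z944]
  diabetes_without_complication:
    weight: 1
    codes: [E100, E101, E106, E108, E109, E110, E111, E116, E118, E119,
            E120, E121, E126, E128, E129, E130, E131, E136, E138, E139,
            E140, E141, E146, E148, E149]
  diabetes_with_complication:
    weight: 2
    codes: [E102, E103, E104, E105, E107, E112, E113, E114, E115, E117,
            E122, E123, E124, E125, E127, E132, E133, E134, E135, E137,
            E142, E143, E144, E145, E147]
  hemiplegia_paraplegia:
    weight: 2
    codes: [G041, G114, G801, G802, G81, G82, G830, G831, G832, G833,
            G834, G839]
  renal_disease:
    weight: 2
    codes: [I120, I131, N032, N033, N034, N035, N036, N037, N052, N053,
            N054, N055, N056, N057, N18, N19, N250, Z490, Z491, Z492,
            Z940, Z992]
  any_malignancy:
    weight: 2
    codes: [C00, C01, C02, C03, C04, C05, C06, C07, C08, C09, C10, C11,
            C12, C13, C14, C15, C16, C17, C18, C19, C20, C21, C22, C23,
            C24, C25, C26, C30, C31, C32, C33, C34, C37, C38, C39, C40,
            C41, C43, C45, C46, C47, C48, C49, C50, C51, C52, C53, C54,
            C55, C56, C57, C58, C60, C61, C62, C63, C64, C65, C66, C67,
            C68, C69, C70, C71, C72, C73, C74, C75, C76, C81, C82, C83,
            C84, C85, C88, C90, C91, C92, C93, C94, C95, C96, C97]
  moderate_severe_liver_disease:
    weight: 3
    codes: [I850, I859, I864, I982, K704, K711, K721, K729, K765, K766,
            K767]
  metastatic_solid_tumour:
    weight: 6
    codes: [C77, C78, C79, C80]
  aids_hiv:
    weight: 6
    codes: [B20, B21, B22, B24]

hierarchy:
  diabetes_with_complication: diabetes_without_complication
  moderate_severe_liver_disease: mild_liver_disease
  metastatic_solid_tumour: any_malignancy

safety_events:
  atrial_fibrillation: [I48]
  hypertension: [I10, I11, I12, I13, I15]
  bleeding: [I60, I61, I62, K920, K921, K922, R58, D62, H113, K625, N02]
  cardiac_arrest: [I46]
  paroxysmal_tachycardia: [I47]
  heart_failure: [I50]
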