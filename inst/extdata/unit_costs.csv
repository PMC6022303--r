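resource_type,unit_cost_gbp,source_note
gp_visit,45,illustrative primary-care consultation tariff (2014 GBP)
practice_nurse,14,illustrative practice-nurse consultation tariff
physiotherapist,34,illustrative community physiotherapy contact
ae_attendance,120,illustrative accident-and-emergency attendance
inpatient_day,600,illustrative inpatient bed-day
outpatient_appointment,135,illustrative outpatient appointment
prescription,9,illustrative mean cost per affected prescription category
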