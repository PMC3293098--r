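id,label,kind,mean,low,high,source
p_trained,Abortion induced by trained provider,probability,0.56,0.38,0.92,Table 1 / provider survey
p_untrained,Abortion induced by untrained provider,probability,0.44,0.21,0.52,Table 1 / provider survey
p_doctor,Doctor given trained provider,probability,0.36,0.29,0.43,Table 1 / provider survey
p_clinical_officer,Clinical officer given trained provider,probability,0.30,0.24,0.37,Table 1 / provider survey
p_nurse_midwife,Nurse or midwife given trained provider,probability,0.34,0.27,0.41,Table 1 / provider survey
p_dispenser,Dispenser given untrained provider,probability,0.16,0.13,0.19,Table 1 / provider survey
p_lay_practitioner,Lay practitioner given untrained provider,probability,0.50,0.40,0.60,Table 1 / provider survey
p_self_induction,Self-induction given untrained provider,probability,0.34,0.27,0.41,Table 1 / provider survey
p_fail_trained,Abortion failure with trained provider,probability,0.0005,0.0002,0.0007,Table 1 / literature
p_fail_untrained,Abortion failure with untrained provider,probability,0.17,0.14,0.21,Table 1 / primary cohort
p_comp_doctor,Complications after doctor abortion,probability,0.25,0.17,0.32,Table 1 / provider survey
p_comp_clinical_officer,Complications after clinical-officer abortion,probability,0.45,0.33,0.48,Table 1 / provider survey
p_comp_nurse_midwife,Complications after nurse/midwife abortion,probability,0.42,0.35,0.43,Table 1 / provider survey
p_comp_dispenser,Complications after dispenser abortion,probability,0.50,0.45,0.52,Table 1 / provider survey
p_comp_lay_practitioner,Complications after lay-practitioner abortion,probability,0.66,0.60,0.68,Table 1 / provider survey
p_comp_self_induction,Complications after self-induced abortion,probability,0.73,0.66,0.75,Table 1 / provider survey
p_hospital_care,Complications need hospital treatment,probability,0.44,0.35,0.52,Table 1 / provider survey
p_outpatient_care,Complications need out-patient treatment,probability,0.56,0.45,0.68,Table 1 / provider survey
p_access,Access to care for complications,probability,0.67,0.51,0.83,Table 1 / provider survey
p_mort_hospital,In-hospital abortion-related mortality,probability,0.02,0.01,0.03,Table 1 / hospital studies
p_mort_community,Community abortion-related mortality,probability,0.05,0.03,0.07,Table 1 / assumption
p_births,Birth after failed abortion,probability,0.87,0.69,1.00,Table 1 / literature
p_miscarriage_13_22,Miscarriage 13-22 weeks after failed abortion,probability,0.03,0.02,0.04,Table 1 / literature
p_miscarriage_lt13,Miscarriage before 13 weeks after failed abortion,probability,0.10,0.08,0.12,Table 1 / assumption
p_facility_delivery,Delivery in a health facility,probability,0.393,0.23,0.58,Table 1 / DHS
p_delivery_mort_facility,Mortality at facility delivery,probability,0.007,0.005,0.008,Table 1 / facility study
p_delivery_mort_community,Mortality at home delivery,probability,0.013,0.011,0.016,Table 1 / assumption
c_proc_doctor,Abortion procedure fee: doctor,cost,93.97,51.51,149.14,Table 2 / provider survey
c_proc_clinical_officer,Abortion procedure fee: clinical officer,cost,55.68,38.12,82.26,Table 2 / provider survey
c_proc_nurse_midwife,Abortion procedure fee: nurse/midwife,cost,42.13,28.09,62.01,Table 2 / provider survey
c_proc_dispenser,Abortion procedure fee: dispenser,cost,17.05,10.03,28.09,Table 2 / provider survey
c_proc_lay_practitioner,Abortion procedure fee: lay practitioner,cost,37.12,24.08,58.16,Table 2 / provider survey
c_proc_self_induction,Abortion procedure fee: self-induction,cost,11.54,8.03,18.06,Table 2 / provider survey
c_proc_productivity,Productivity loss while procuring abortion,cost,1.14,0.57,2.29,Table 2 / primary study
c_hosp_personnel,Hospital complication treatment: personnel,cost,19.31,9.74,38.63,Table 2 / costing study
c_hosp_supplies,Hospital complication treatment: supplies,cost,11.45,10.94,11.85,Table 2 / primary study
c_hosp_drugs,Hospital complication treatment: drugs,cost,6.67,5.60,8.30,Table 2 / primary study
c_hosp_diagnostics,Hospital complication treatment: diagnostic tests,cost,14.94,14.31,15.41,Table 2 / primary study
c_hosp_overhead,Hospital complication treatment: overhead and capital,cost,10.35,8.67,12.04,Table 2 / WHO-CHOICE
c_hosp_productivity,Productivity loss: hospital complication episode,cost,23.76,20.52,32.84,Table 2 / primary study
c_outpt_personnel,Out-patient complication treatment: personnel,cost,1.01,0.51,2.04,Table 2 / costing study
c_outpt_supplies,Out-patient complication treatment: supplies,cost,1.50,0.71,2.97,Table 2 / primary study
c_outpt_drugs,Out-patient complication treatment: drugs,cost,1.20,1.14,1.36,Table 2 / primary study
c_outpt_diagnostics,Out-patient complication treatment: diagnostic tests,cost,4.98,4.31,5.20,Table 2 / primary study
c_outpt_overhead,Out-patient complication treatment: overhead and capital,cost,1.95,0.97,3.89,Table 2 / WHO-CHOICE
c_outpt_productivity,Productivity loss: out-patient complication episode,cost,1.14,0.57,2.29,Table 2 / primary study
c_anc,Antenatal care package,cost,10.09,5.05,20.18,Table 2 / costing study
c_hospital_delivery,Hospital delivery,cost,116.63,58.32,233.26,Table 2 / costing study
c_transport,Patient transport (per care-seeking episode),cost,2.49,1.42,3.03,Table 2 / primary study
c_upkeep,Patient upkeep (per care-seeking episode),cost,11.59,9.11,14.06,Table 2 / primary study
c_out_of_pocket,Out-of-pocket payment for complication treatment,cost,1.48,0.74,2.95,Table 2 / primary study
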