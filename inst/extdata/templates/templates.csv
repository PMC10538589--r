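role,text
hpi_filler,"The patient is a [**Age over 90 **]-year-old admitted from the emergency department."
hpi_filler,"Past medical history includes hypertension and diabetes mellitus."
hpi_filler,"Home medications were reviewed on admission."
hpi_filler,"The patient presented after a mechanical fall at home."
filler,"The patient remained afebrile overnight."
filler,"Vital signs were stable throughout the day."
filler,"Telemetry showed normal sinus rhythm."
filler,"Laboratory studies were within normal limits."
filler,"The patient ambulated in the hallway with assistance."
filler,"Diet was advanced as tolerated."
filler,"Physical therapy evaluated the patient at the bedside."
filler,"The remainder of the stay was uneventful."
drug_carrier,"{DRUG} was administered for analgesia during the stay."
drug_carrier,"{DRUG} was continued at the usual dose."
drug_carrier,"The team started {DRUG} on hospital day one."
ae_carrier,"Nursing documented {AE} overnight."
ae_carrier,"The patient developed {AE} on hospital day two."
ae_carrier,"Examination revealed {AE} that morning."
anchor_drug_ae,"On review, {DRUG} {TRIGGER} the {AE} per the team."
anchor_drug,"{DRUG} was held as it was felt {TRIGGER} the clinical picture."
anchor_plain,"The team felt the medication was {TRIGGER} the clinical picture."
anchor_ae,"The {AE} was felt to be {TRIGGER} the opioid regimen."
antidote_anchor,"{ANTIDOTE} was administered with rapid improvement."
antidote_anchor_ae,"{ANTIDOTE} was given for {AE} with rapid improvement."
indication,"{DRUG} was started due to {PAIN_AE}."
indication,"The patient received {DRUG} due to {PAIN_AE}."
switch,"The service switched to {DRUG} due to {AE}, which resolved."
switch,"She was changed to {DRUG} due to {AE}, which resolved."
negation_ae,"No further {AE} attributed to the medication."
negation_ae,"The patient denied {AE} attributed to the medication."
discharge_med,"Atorvastatin 40 mg daily."
discharge_med,"Lisinopril 10 mg daily."
discharge_med,"Docusate sodium 100 mg twice daily."
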