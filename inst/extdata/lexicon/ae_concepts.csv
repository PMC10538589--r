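concept_id,preferred_term,lower_level_term,synonym
C001,Mental state abnormal,Altered mental status,mental state abnormal
C001,Mental state abnormal,Altered mental status,altered mental status
C001,Mental state abnormal,Altered mental status,altered mental state
C001,Mental state abnormal,Altered mental status,mental status change
C001,Mental state abnormal,Altered mental status,mental status changes
C002,Respiratory arrest,,respiratory arrest
C002,Respiratory arrest,,apneic arrest
C003,Respiratory depression,,respiratory depression
C003,Respiratory depression,,respiratory suppression
C003,Respiratory depression,,hypoventilation
C004,Apnoea,Apneic episode,apnoea
C004,Apnoea,Apneic episode,apnea
C004,Apnoea,Apneic episode,apneic event
C004,Apnoea,Apneic episode,apneic events
C004,Apnoea,Apneic episode,apneic episode
C004,Apnoea,Apneic episode,apneic episodes
C005,Hypotension,Low blood pressure,hypotension
C005,Hypotension,Low blood pressure,hypotensive
C005,Hypotension,Low blood pressure,low blood pressure
C006,Somnolence,Drowsiness,somnolence
C006,Somnolence,Drowsiness,somnolent
C006,Somnolence,Drowsiness,drowsiness
C006,Somnolence,Drowsiness,drowsy
C006,Somnolence,Drowsiness,sleepiness
C007,Nausea,,nausea
C007,Nausea,,nauseated
C007,Nausea,,nauseous
C008,Vomiting,Emesis,vomiting
C008,Vomiting,Emesis,vomited
C008,Vomiting,Emesis,emesis
C009,Confusional state,Confusion,confusional state
C009,Confusional state,Confusion,confusion
C009,Confusional state,Confusion,confused
C009,Confusional state,Confusion,disorientation
C009,Confusional state,Confusion,disoriented
C010,Delirium,,delirium
C010,Delirium,,delirious
C011,Agitation,,agitation
C011,Agitation,,agitated
C012,Constipation,,constipation
C012,Constipation,,constipated
C012,Constipation,,severe constipation
C012,Constipation,,severely constipated
C013,Sedation,Oversedation,sedation
C013,Sedation,Oversedation,sedated
C013,Sedation,Oversedation,oversedation
C013,Sedation,Oversedation,over sedation
C013,Sedation,Oversedation,oversedated
C014,Pruritus,Itching,pruritus
C014,Pruritus,Itching,itching
C014,Pruritus,Itching,itchiness
C014,Pruritus,Itching,itchy
C015,Urinary retention,,urinary retention
C016,Ileus,,ileus
C017,Hypersomnia,Hypersomnolence,hypersomnia
C017,Hypersomnia,Hypersomnolence,hypersomnolence
C017,Hypersomnia,Hypersomnolence,daytime hypersomnolence
C018,Headache,Morning headache,headache
C018,Headache,Morning headache,headaches
C018,Headache,Morning headache,morning headache
C018,Headache,Morning headache,morning headaches
C019,Dizziness,,dizziness
C019,Dizziness,,dizzy
C019,Dizziness,,lightheadedness
C019,Dizziness,,lightheaded
C020,Dyspnoea,Shortness of breath,dyspnoea
C020,Dyspnoea,Shortness of breath,dyspnea
C020,Dyspnoea,Shortness of breath,shortness of breath
C021,Bradypnoea,,bradypnoea
C021,Bradypnoea,,bradypnea
C022,Back pain,,back pain
C022,Back pain,,low back pain
C023,Abdominal pain,,abdominal pain
C023,Abdominal pain,,stomach pain
C024,Pain,,pain
C025,Urticaria,Hives,urticaria
C025,Urticaria,Hives,hives
C026,Bradycardia,,bradycardia
C027,Lethargy,,lethargy
C027,Lethargy,,lethargic
C028,Unresponsive to stimuli,Unresponsiveness,unresponsive to stimuli
C028,Unresponsive to stimuli,Unresponsiveness,unresponsive
C028,Unresponsive to stimuli,Unresponsiveness,unresponsiveness
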