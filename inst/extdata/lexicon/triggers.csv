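phrase,source
secondary to,published_base
due to,published_base
related to,published_base
associated with,published_base
caused by,published_base
as a result of,published_base
attributed to,published_base
side effect,published_base
adverse effect,published_base
adverse reaction,published_base
toxicity,published_base
drug induced,published_base
iatrogenic,published_base
complication of,published_base
contributed to,curated
contributing to,curated
with subsequent,curated
subsequently developed,curated
likely due to,curated
possibly due to,curated
probably due to,curated
presumably due to,curated
thought to be due to,curated
felt to be due to,curated
felt to be secondary to,curated
thought to be secondary to,curated
likely secondary to,curated
possibly secondary to,curated
in the setting of,curated
in the context of,curated
after receiving,curated
after starting,curated
following administration of,curated
following initiation of,curated
exacerbated by,curated
worsened by,curated
precipitated by,curated
triggered by,curated
induced by,curated
likely from,curated
possibly from,curated
resulting from,curated
resulting in,curated
resulted in,curated
as a consequence of,curated
consequence of,curated
sequela of,curated
sequelae of,curated
stemming from,curated
linked to,curated
concerning for,curated
suspicious for,curated
attributable to,curated
ascribed to,curated
blamed on,curated
implicated in,curated
offending agent,curated
culprit medication,curated
held due to,curated
held in the setting of,curated
discontinued due to,curated
stopped due to,curated
dose reduced due to,curated
in the face of,curated
temporally related to,curated
temporal relation to,curated
coincided with,curated
coinciding with,curated
likely related to,curated
possibly related to,curated
reaction to,curated
effect of,curated
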