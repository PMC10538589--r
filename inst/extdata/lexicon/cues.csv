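cue,type
no,negation
no further,negation
denies,negation
denied,negation
without,negation
not,negation
negative for,negation
never had,negation
never developed,negation
free of,negation
but,termination
however,termination
although,termination
though,termination
except,termination
aside from,termination
other than,termination
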