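# Shared lexical constants; in their own file so every later-collating file
# can use them at load time.

TIME_UNIT_RE <- "(?:hours?|hrs?|h|days?|d|weeks?|wks?|months?|mos?|years?|yrs?)"
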