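animal_id,timestamp,lat,lon,dop
W01,2019-06-15T08:00:00Z,50.0000,14.8000,2.0
W01,2019-06-15T08:30:00Z,50.0000,14.8070,2.0
W01,2019-06-15T09:00:00Z,50.0045,14.8070,2.0
W01,2019-06-15T09:30:00Z,50.0045,14.8000,2.0
W01,2019-06-15T10:00:00Z,50.0000,14.8000,2.0
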