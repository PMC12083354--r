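workflow,metric,centre,value
DR,CDR,centre1,8.9
DR,CDR,centre2,8.9
DR,CDR,centre3,6.6
DR,RR,centre1,5.0
DR,RR,centre2,5.0
DR,RR,centre3,3.3
sIR,RR,centre1,4.5
sIR,RR,centre2,4.6
sIR,RR,centre3,3.2
DRT,RR,centre1,4.6
DRT,RR,centre2,4.5
DRT,RR,centre3,3.1
sIR,WORKLOAD_SAVING,centre1,41.0
sIR,WORKLOAD_SAVING,centre2,42.9
sIR,WORKLOAD_SAVING,centre3,43.7
DRT,WORKLOAD_SAVING,centre1,38.3
DRT,WORKLOAD_SAVING,centre2,39.6
DRT,WORKLOAD_SAVING,centre3,41.0
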