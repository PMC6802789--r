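# example of the trial CSV layout; one subject, hand-constructed
subject_id,experiment,block,trial_index,cue_type,cue_symbol,soa_ms,target_present,target_side,target_colour_deg,wheel_rotation_deg,response_colour_deg,rt_ms,outcome
s01,E1,0,1,valid,2,800,TRUE,right,10,0,15,340,hit
s01,E1,0,2,neutral,H,800,TRUE,left,200,45,205,360,hit
s01,E1,1,3,valid,2,800,TRUE,right,350,10,10,350,hit
s01,E1,1,4,valid,2,800,TRUE,right,10,20,355,350,hit
s01,E1,1,5,valid,5,800,TRUE,left,123.4,30,123.4,350,hit
s01,E1,1,6,valid,5,800,TRUE,left,0,40,180,350,hit
s01,E1,1,7,valid,2,800,TRUE,right,100,50,105,350,hit
s01,E1,1,8,valid,2,800,TRUE,right,100,60,95,350,hit
s01,E1,1,9,valid,5,800,TRUE,left,200,70,210,350,hit
s01,E1,1,10,valid,5,800,TRUE,left,200,80,190,350,hit
s01,E1,1,11,valid,2,800,TRUE,right,300,90,302,350,hit
s01,E1,1,12,valid,2,800,TRUE,right,300,100,298,350,hit
s01,E1,1,13,valid,5,800,TRUE,left,45,110,53,350,hit
s01,E1,1,14,valid,5,800,TRUE,left,45,120,37,350,hit
s01,E1,1,15,valid,2,800,TRUE,right,77,130,,,miss
s01,E1,1,16,valid,2,800,FALSE,none,,140,123,400,false_alarm
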