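"turtle_id","lag_index","lag_diameter_mm","is_double","section_diameter_mm","resorption_diameter_mm","otc_diameter_mm"
"CM-1",1,22.4263910180754,FALSE,23.8829416785224,11.2131955090377,22.7684364831627
"CM-1",2,23.1965806938314,FALSE,23.8829416785224,11.2131955090377,22.7684364831627
"CM-4",1,28.4249711968618,FALSE,28.68636781964,14.2124855984309,28.5992145620604
"CM-4",2,28.68536781964,FALSE,28.68636781964,14.2124855984309,28.5992145620604
"CM-6",1,22.5973610953072,FALSE,22.9396164165108,11.2986805476536,
"CM-6",2,22.9386164165108,FALSE,22.9396164165108,11.2986805476536,
"CM-8",1,28.6427885658916,FALSE,28.8607371839722,14.3213942829458,
"CM-8",2,28.8597371839722,FALSE,28.8607371839722,14.3213942829458,
"CM-9",1,17.727417202584,FALSE,17.9370469242791,8.86370860129199,
"CM-9",2,17.8531701189758,FALSE,17.9370469242791,8.86370860129199,
"CM-10",1,35.2788248311515,FALSE,35.6776511968162,17.6394124155757,
"CM-10",2,35.5003520384913,FALSE,35.6776511968162,17.6394124155757,
"CM-11",1,22.2982330371493,FALSE,23.3251496255664,11.1491165185746,22.3836650443324
"CM-11",2,22.554608672984,FALSE,23.3251496255664,11.1491165185746,22.3836650443324
"CM-11",3,22.8112216949931,FALSE,23.3251496255664,11.1491165185746,22.3836650443324
"CM-11",4,23.0252453517913,FALSE,23.3251496255664,11.1491165185746,22.3836650443324
"CM-11",5,23.2394306020085,FALSE,23.3251496255664,11.1491165185746,22.3836650443324
"CM-12",1,23.4395586990562,TRUE,24.6139497885251,11.7197793495281,23.5395586990562
"CM-12",2,23.5395586990562,TRUE,24.6139497885251,11.7197793495281,23.5395586990562
"CM-12",3,23.7970582763412,FALSE,24.6139497885251,11.7197793495281,23.5395586990562
"CM-12",4,24.0547832773072,FALSE,24.6139497885251,11.7197793495281,23.5395586990562
"CM-12",5,24.2697246347872,FALSE,24.6139497885251,11.7197793495281,23.5395586990562
"CM-12",6,24.484819608011,FALSE,24.6139497885251,11.7197793495281,23.5395586990562
"CM-13",1,20.0019922490967,FALSE,28.6427885658916,19.6213252704612,18.9882462221028
"CM-13",2,21.0200103531454,FALSE,28.6427885658916,19.6213252704612,18.9882462221028
"CM-13",3,22.0420974298594,FALSE,28.6427885658916,19.6213252704612,18.9882462221028
"CM-13",4,23.0680695207173,FALSE,28.6427885658916,19.6213252704612,18.9882462221028
"CM-13",5,24.0977591966917,FALSE,28.6427885658916,19.6213252704612,18.9882462221028
"CM-13",6,25.1310134004805,FALSE,28.6427885658916,19.6213252704612,18.9882462221028
"CM-13",7,26.1676916507477,FALSE,28.6427885658916,19.6213252704612,18.9882462221028
"CM-13",8,27.2076645352615,FALSE,28.6427885658916,19.6213252704612,18.9882462221028
"CM-13",9,28.2508124368856,FALSE,28.6427885658916,19.6213252704612,18.9882462221028
"CM-14",1,20.5802092691097,TRUE,21.8288363947781,10.2901046345548,20.6802092691097
"CM-14",2,20.6802092691097,TRUE,21.8288363947781,10.2901046345548,20.6802092691097
"CM-14",3,20.9775103549508,FALSE,21.8288363947781,10.2901046345548,20.6802092691097
"CM-14",4,21.2751581472641,FALSE,21.8288363947781,10.2901046345548,20.6802092691097
"CM-14",5,21.5305571828833,FALSE,21.8288363947781,10.2901046345548,20.6802092691097
"CM-14",6,21.7435795356302,FALSE,21.8288363947781,10.2901046345548,20.6802092691097
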