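label,category,unit,n_units,unit_cost_kes
Counselor supervisor consultants: 2-week training plus 5 days prep (4 consultants),Counselor consultants,day of pay,76,2000
Supervision after training (12 sites x 18 weeks x 1 day/week),Counselor consultants,day of pay,216,2000
Travel to sites (12 sites x 18 weeks x 1 day/week),Counselor consultants,day of travel,216,1000
Phone consultation after training (2 calls/site/month for 8 months),Counselor consultants,phone call,192,300
Medical/psychiatry trainers: 10-day training of diploma nurses,Psychiatry,day of training,10,10000
Consultation after training (10% FTE for 5 years for one physician),Psychiatry,year salary,0.5,1440000
Per diems: counselors (12 days x 24 counselors),Per diems,trainee-day,288,3500
Per diems: diploma nurses (10 days x 12 nurses),Per diems,trainee-day,120,3500
Training workbooks and treatment manuals,Training materials,piece,43,900
Audiorecorders,Training materials,piece,12,4000
Rechargeable batteries,Training materials,piece,24,200
Battery chargers,Training materials,piece,12,1040
Posters,Training materials,piece,36,1100
Sharp pointed pens,Training materials,packet,2,500
Whiteboard markers,Training materials,packet,2,1200
Facility rental,Conference center,day of room rental,12,12000
Lunch and tea (participants x days),Conference center,lunch,486,900
File cabinets,Furniture,piece,12,16500
Stacking plastic chairs,Furniture,piece,144,800
Whiteboards,Furniture,piece,12,8500
Cellphones for assessment calls,Equipment,piece,12,4000
Cashboxes,Equipment,piece,12,5999
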