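label,category,unit,n_units,unit_cost_kes
Diploma nurse (25% FTE),Personnel,annual salary,0.25,444240
Counselors (2 at 100% FTE),Personnel,annual salary,2,201840
Sharp pointed pens,Supplies,packet,2,500
Whiteboard markers,Supplies,packet,2,1200
Airtime for assessment coordinator (500 KES/week x 40 weeks),Supplies,annual allowance,1,20000
Airtime for physician consultation (4 calls x 40 weeks),Supplies,phone call,160,50
Box files,Supplies,piece,5,155
Suspension files,Supplies,box,2,3500
Photocopies,Supplies,copy,2000,3
Benzodiazepines (10% of patients per year),Supplies,patient,16,24
Multivitamins,Supplies,patient,16,16
Participant payments (160 participants x 6 visits),Participant Payments,visit,960,200
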