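approval_id,drug,route,indication,year,manufacturer,comparative_evidence_required,continuation_evidence_required,subgroup_basis,bias_assessment,safety_comparison_active,safety_comparison_placebo,safety_issue,tolerance_comparison_active,tolerance_comparison_placebo,tolerance_issue,divergent_opinion,n_exposed_presubmission,approved_dose_min,approved_dose_max
A01,olanzapine,oral,schizophrenia,2001,,TRUE,TRUE,none,reported_no_bias,quantitative,quantitative,yes,quantitative,quantitative,yes,FALSE,987,5,20
A02,varenicline,oral,smoking cessation,2006,,TRUE,TRUE,none,reported_no_bias,quantitative,quantitative,no,quantitative,quantitative,no,FALSE,1074,5,20
A03,drug03,oral,major depressive disorder,2011,,TRUE,TRUE,none,none_reported,quantitative,quantitative,no,quantitative,quantitative,no,FALSE,1161,5,20
A04,drug04,oral,schizophrenia,2016,,TRUE,TRUE,none,none_reported,quantitative,quantitative,possible,quantitative,quantitative,yes,FALSE,1248,5,20
A05,drug05,oral,bipolar disorder,2000,,TRUE,TRUE,none,none_reported,quantitative,quantitative,no,quantitative,quantitative,possible,FALSE,1335,5,20
A06,drug06,oral,generalised anxiety disorder,2005,,TRUE,TRUE,none,none_reported,quantitative,quantitative,no,quantitative,quantitative,no,FALSE,1422,5,20
A07,drug07,oral,schizophrenia,2010,,TRUE,TRUE,none,none_reported,quantitative,qualitative,no,quantitative,qualitative,no,FALSE,1509,5,20
A08,drug08,oral,major depressive disorder,2015,,TRUE,TRUE,none,none_reported,quantitative,qualitative,no,quantitative,quantitative,no,FALSE,1596,5,20
A09,drug09,intramuscular,schizophrenia,1999,,TRUE,TRUE,none,none_reported,absent,quantitative,possible,quantitative,quantitative,no,FALSE,1683,5,20
A10,drug10,intramuscular,schizophrenia,2004,,TRUE,TRUE,none,none_reported,absent,quantitative,no,quantitative,quantitative,no,FALSE,1770,5,20
A11,drug11,intramuscular,bipolar disorder,2009,,TRUE,TRUE,none,none_reported,absent,quantitative,no,quantitative,quantitative,no,FALSE,1857,5,20
A12,drug12,intramuscular,schizophrenia,2014,,TRUE,TRUE,none,none_reported,quantitative,quantitative,no,quantitative,quantitative,no,FALSE,1944,5,20
A13,drug13,intramuscular,major depressive disorder,1998,,TRUE,TRUE,none,none_reported,quantitative,quantitative,no,quantitative,quantitative,possible,FALSE,2031,5,20
A14,drug14,intramuscular,bipolar disorder,2003,,TRUE,TRUE,none,none_reported,quantitative,quantitative,no,quantitative,quantitative,no,FALSE,2118,5,20
A15,drug15,oral,schizophrenia,2008,,TRUE,TRUE,none,none_reported,quantitative,absent,no,quantitative,absent,no,FALSE,2205,5,20
A16,drug16,intramuscular,schizophrenia,2013,,TRUE,TRUE,none,none_reported,quantitative,absent,no,quantitative,quantitative,no,FALSE,2292,5,20
A17,paliperidone,oral,schizoaffective disorder,1997,,TRUE,TRUE,post_hoc,none_reported,quantitative,absent,no,quantitative,quantitative,no,FALSE,2379,5,20
A18,agomelatine,oral,major depressive disorder,2002,,TRUE,TRUE,none,none_reported,qualitative,absent,yes,qualitative,quantitative,no,TRUE,2466,5,20
A19,duloxetine,oral,major depressive disorder,2007,,TRUE,TRUE,none,reported_no_bias,qualitative,quantitative,no,quantitative,quantitative,no,FALSE,2553,5,20
A20,paliperidone,intramuscular,maintenance treatment of schizophrenia,2012,,TRUE,TRUE,none,none_reported,quantitative,quantitative,possible,quantitative,quantitative,no,FALSE,2640,5,20
A21,duloxetine,oral,generalised anxiety disorder,1996,,TRUE,TRUE,none,none_reported,quantitative,quantitative,no,quantitative,quantitative,no,FALSE,2727,5,20
A22,drug22,inhalation,agitation,2001,,TRUE,FALSE,none,none_reported,absent,quantitative,yes,absent,quantitative,no,FALSE,2814,5,20
A23,drug23,sublingual,agitation,2006,,TRUE,FALSE,none,none_reported,absent,quantitative,no,absent,quantitative,no,FALSE,2901,5,20
A24,drug24,sublingual,agitation,2011,,TRUE,FALSE,none,none_reported,absent,quantitative,no,absent,quantitative,no,FALSE,2988,5,20
A25,drug25,oral,agitation,2016,,TRUE,FALSE,none,none_reported,quantitative,quantitative,no,absent,quantitative,no,FALSE,3075,5,20
A26,drug26,oral,agitation,2000,,TRUE,FALSE,none,none_reported,quantitative,quantitative,no,quantitative,quantitative,no,FALSE,3162,5,20
A27,nalmefene,oral,alcohol use disorders,2005,,FALSE,TRUE,post_hoc,none_reported,absent,quantitative,no,absent,quantitative,no,FALSE,3249,5,20
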