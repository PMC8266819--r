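season,category,edec_pct
spring,Cultivated fleshy fruits,5
spring,Cultivated vegetables,5
spring,Formicidae,5
spring,Hard mast,20
spring,Herbs,40
spring,Ungulates,15
spring,Wild fleshy fruits,10
early_summer,Cultivated fleshy fruits,5
early_summer,Cultivated vegetables,5
early_summer,Formicidae,35
early_summer,Hard mast,5
early_summer,Herbs,25
early_summer,Ungulates,10
early_summer,Wild fleshy fruits,15
late_summer,Cultivated fleshy fruits,15
late_summer,Cultivated vegetables,5
late_summer,Formicidae,10
late_summer,Hard mast,10
late_summer,Herbs,10
late_summer,Ungulates,5
late_summer,Wild fleshy fruits,45
autumn,Cultivated fleshy fruits,15
autumn,Cultivated vegetables,5
autumn,Formicidae,2.5
autumn,Hard mast,55
autumn,Herbs,5
autumn,Ungulates,2.5
autumn,Wild fleshy fruits,15
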