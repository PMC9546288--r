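trial,treatment,runoff_mm,cn_event,erosion_kg_ha
2018,CvT,7.3,75,2371
2018,MD+CvT,4.2,72,1046
2018,CsT,1.2,67,62
2018,MD+CsT,0.7,66,34
2019,CvT,9.7,73,6655
2019,MD+CvT,3.3,70,1203
2019,CsT,3.0,66,599
2019,MD+CsT,1.5,65,204
2013-16,CvT,7.3,69,1030
2013-16,Disc plow (MD),5.5,68,480
2013-16,Drum plow (MD),2.3,63,260
2013-16,CsT,0.78,63,17
2013-9,CvT,4.8,67,420
2013-9,Disc plow (MD),2.5,66,170
2013-9,Drum plow (MD),1.4,64,80
2013-9,CsT,0.62,63,17
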