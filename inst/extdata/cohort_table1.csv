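shark_id,length_cm,girth_cm,sex,duration_h,dates,adl_model,site,note
Shark 01,79,32,M,24,23-24 Jun 2016,Cefas G6a+,BFC,
Shark 02,59,24,M,24,11-12 Jul 2016,Cefas G6a+,BFC,logger_malfunction
Shark 03,70,27,F,24,18-19 Jul 2016,Cefas G6a+,IR,
Shark 04,76,34,F,13,28-29 Jul 2016,Cefas G6a+,BR,tag_loss
Shark 05,73,31,M,24,01-02 Aug 2016,Cefas G6a+,BR,
Shark 06,76,36,F,24,05-06 Aug 2016,Cefas G6a+,BR,
Shark 07,74,32,M,24,08-09 Aug 2016,Cefas G6a+,IR,track_loss
Shark 08,61,23,M,24,11-12 Aug 2016,Cefas G6a+,IR,
Shark 09,72.5,33,F,24,02-03 Sep 2016,Cefas G6a+,IR,
Shark 10,71,34,F,48,07-09 Jun 2017,TechnoSmArt Axy-Depth,BFC,
Shark 11,71,32,F,48,14-16 Jun 2017,TechnoSmArt Axy-Depth,BFC,
Shark 12,66.5,26,F,48,27-29 Jun 2017,TechnoSmArt Axy-Depth,IR,
Shark 13,77,35,M,48,02-04 Aug 2017,TechnoSmArt Axy-Depth,IR,
Shark 14,70,31,F,48,09-11 Aug 2017,TechnoSmArt Axy-Depth,IR,
Shark 15,89,37.5,F,48,16-18 Aug 2017,TechnoSmArt Axy-Depth,BFC,logger_malfunction
Shark 16,74,37,F,48,23-25 Aug 2017,TechnoSmArt Axy-Depth,CG,
Shark 17,75,35,F,48,28-30 Aug 2017,TechnoSmArt Axy-Depth,CG,
Shark 18,75,35,F,48,11-13 Sep 2017,TechnoSmArt Axy-Depth,CG,
Shark 19,74,35,M,38,02-03 Oct 2017,TechnoSmArt Axy-Depth,BFC,
Shark 20,78,33,M,48,05-07 Oct 2017,TechnoSmArt Axy-Depth,BFC,
Shark 21,76.5,33,F,48,23-25 Oct 2017,TechnoSmArt Axy-Depth,BFC,
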